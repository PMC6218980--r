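#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with a linear gap model and full traceback.
//
// Scoring: +match for identical A/C/G/T columns, +mismatch for substituted
// columns, +gap per gap column. 'N' never matches anything (scores as a
// mismatch, including N vs N) so runs of ambiguity cannot create spurious
// palindrome hits.
//
// Tie-breaking is fully deterministic: cell-level traceback prefers
// diagonal, then up (gap in target), then left (gap in query); among
// equal-scoring end cells the alignment with the smallest q_start, then
// smallest t_start, then smallest q_end, then smallest t_end wins.

static inline bool base_match(char a, char b) {
    return a == b && a != 'N';
}

struct TbResult {
    int q_start, t_start, matches, columns;
    std::string path; // per column: '=' match, 'X' mismatch, 'D' query-only, 'I' target-only
};

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap) {
    const int n = (int) query.size();
    const int m = (int) target.size();
    if (n == 0 || m == 0)
        stop("sw_align: sequences must be non-empty");

    // H stored row-by-row so traceback can re-read scores; memory is
    // (n+1)*(m+1) ints, i.e. quadratic in read length.
    std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
    int best = 0;

    for (int i = 1; i <= n; ++i) {
        const char qi = query[i - 1];
        const size_t row = (size_t) i * (m + 1);
        const size_t prev = (size_t)(i - 1) * (m + 1);
        for (int j = 1; j <= m; ++j) {
            const int s = base_match(qi, target[j - 1]) ? match : mismatch;
            int h = H[prev + j - 1] + s;
            const int up = H[prev + j] + gap;
            const int left = H[row + j - 1] + gap;
            if (up > h) h = up;
            if (left > h) h = left;
            if (h < 0) h = 0;
            H[row + j] = h;
            if (h > best) best = h;
        }
    }

    if (best == 0) {
        return List::create(
            _["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
            _["t_start"] = 0, _["t_end"] = 0,
            _["matches"] = 0, _["columns"] = 0, _["path"] = "");
    }

    // Traceback from one end cell, preferring diag > up > left.
    auto traceback = [&](int ei, int ej) -> TbResult {
        TbResult r;
        r.matches = 0;
        std::string rev;
        int i = ei, j = ej;
        while (i > 0 && j > 0) {
            const int h = H[(size_t) i * (m + 1) + j];
            if (h == 0) break;
            const int s = base_match(query[i - 1], target[j - 1]) ? match : mismatch;
            const int diag = H[(size_t)(i - 1) * (m + 1) + (j - 1)];
            if (h == diag + s) {
                if (s == match) { rev.push_back('='); ++r.matches; }
                else rev.push_back('X');
                --i; --j;
            } else if (h == H[(size_t)(i - 1) * (m + 1) + j] + gap) {
                rev.push_back('D');
                --i;
            } else {
                rev.push_back('I');
                --j;
            }
        }
        r.q_start = i;
        r.t_start = j;
        r.columns = (int) rev.size();
        r.path.assign(rev.rbegin(), rev.rend());
        return r;
    };

    int bq_start = -1, bt_start = -1, bq_end = -1, bt_end = -1;
    TbResult bestTb;
    for (int i = 1; i <= n; ++i) {
        const size_t row = (size_t) i * (m + 1);
        for (int j = 1; j <= m; ++j) {
            if (H[row + j] != best) continue;
            TbResult tb = traceback(i, j);
            if (bq_start < 0 ||
                tb.q_start < bq_start ||
                (tb.q_start == bq_start && (tb.t_start < bt_start ||
                 (tb.t_start == bt_start && (i < bq_end ||
                  (i == bq_end && j < bt_end)))))) {
                bq_start = tb.q_start; bt_start = tb.t_start;
                bq_end = i; bt_end = j;
                bestTb = tb;
            }
        }
    }

    return List::create(
        _["score"] = best,
        _["q_start"] = bq_start, _["q_end"] = bq_end,
        _["t_start"] = bt_start, _["t_end"] = bt_end,
        _["matches"] = bestTb.matches, _["columns"] = bestTb.columns,
        _["path"] = bestTb.path);
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string seq) {
    const size_t n = seq.size();
    std::string out(n, 'N');
    for (size_t i = 0; i < n; ++i) {
        char c = seq[n - 1 - i], r;
        switch (c) {
        case 'A': r = 'T'; break;
        case 'C': r = 'G'; break;
        case 'G': r = 'C'; break;
        case 'T': r = 'A'; break;
        case 'N': r = 'N'; break;
        default: stop("reverse_complement: invalid base '%s'", std::string(1, c));
        }
        out[i] = r;
    }
    return out;
}
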