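#' Alignment scoring scheme
#'
#' Scores used when a read is aligned against its own reverse complement.
#' The defaults are the parameter set the method was designed around:
#' +3 per identical column, -4 per substitution, -3 per gap column
#' (a single linear gap penalty, no separate open/extend costs).
#'
#' @param match Integer score per identical column (> 0).
#' @param mismatch Integer score per substituted column (< 0). `N` aligned
#'   to anything, including another `N`, scores as a mismatch.
#' @param gap Integer score per gap column, linear model (< 0).
#' @return An object of class `pc_scoring`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(match = 2, mismatch = -3, gap = -2)
#' @export
scoring_scheme <- function(match = 3L, mismatch = -4L, gap = -3L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  if (is.na(match) || match <= 0L) stop("match score must be a positive integer")
  if (is.na(mismatch) || mismatch >= 0L) stop("mismatch score must be negative")
  if (is.na(gap) || gap >= 0L) stop("gap score must be negative")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "pc_scoring")
}

#' Palindrome-hit acceptance thresholds
#'
#' A local self-vs-reverse-complement hit only counts as a detectable
#' palindrome if it clears all five ratios. With the defaults
#' (0.01/0.01/0.01/0.01 and base score 1.0) the operative criterion is
#' `score >= read length`: a hit must accumulate, on average, at least one
#' score unit per base of the read, which random non-palindromic reads do
#' not reach.
#'
#' @param filter_factor Minimum score as a fraction of the maximum
#'   attainable score (`match * read_length`).
#' @param query_coverage Minimum aligned fraction of the read.
#' @param query_identity Minimum identical fraction of aligned columns.
#' @param relative_score Minimum score per alignment column.
#' @param base_score Minimum score per read base.
#' @return An object of class `pc_filters`.
#' @examples
#' filter_thresholds()
#' @export
filter_thresholds <- function(filter_factor = 0.01, query_coverage = 0.01,
                              query_identity = 0.01, relative_score = 0.01,
                              base_score = 1.0) {
  vals <- c(filter_factor, query_coverage, query_identity, relative_score, base_score)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all filter thresholds must be finite and >= 0")
  structure(list(filter_factor = filter_factor, query_coverage = query_coverage,
                 query_identity = query_identity, relative_score = relative_score,
                 base_score = base_score),
            class = "pc_filters")
}

#' Reverse complement of a DNA sequence
#'
#' @param seq Character scalar over `A,C,G,T,N` (case-insensitive).
#' @param lenient If `TRUE`, characters outside the alphabet are mapped to
#'   `N` instead of raising an error.
#' @return The reverse-complemented sequence, uppercased. `N` complements
#'   to `N`.
#' @examples
#' reverse_complement("AACC")  # "GGTT"
#' reverse_complement("ACGT")  # its own reverse complement
#' @export
reverse_complement <- function(seq, lenient = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- clean_sequence(seq, lenient = lenient)
  if (nchar(seq) == 0L) return("")
  revcomp_cpp(seq)
}

# Uppercase and validate/sanitise a sequence string.
clean_sequence <- function(seq, lenient = FALSE) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    if (!lenient) {
      bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
      stop("sequence contains non-IUPAC characters outside {A,C,G,T,N}: ",
           paste(bad, collapse = ", "),
           " (use lenient alphabet handling to map them to N)")
    }
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman dynamic programming with full traceback under a
#' linear gap model. The entire score matrix is kept, so memory grows with
#' the product of the two sequence lengths; sequences longer than
#' `max_length` are refused with a resource error.
#'
#' @param query,target Character scalars over `A,C,G,T,N`.
#' @param scoring A [scoring_scheme()].
#' @param max_length Maximum sequence length accepted (default 100000).
#' @param lenient Passed to sequence validation; see [reverse_complement()].
#' @return An object of class `pc_alignment`: a list with integer fields
#'   `score`, `q_start`, `q_end`, `t_start`, `t_end` (0-based, half-open),
#'   `matches`, `columns`, and `path`, a string with one character per
#'   alignment column (`=` identical, `X` substitution, `D` gap in target,
#'   `I` gap in query). A best score of 0 is returned as an empty alignment
#'   with `columns = 0`.
#' @examples
#' sw_align("ACGTACGT", "ACGTACGT")$score  # 24 = 8 matches x 3
#' sw_align("AAAA", "TTTT")$columns        # 0: no positive-scoring cell
#' @export
sw_align <- function(query, target, scoring = scoring_scheme(),
                     max_length = 100000L, lenient = FALSE) {
  stopifnot(inherits(scoring, "pc_scoring"))
  query <- clean_sequence(query, lenient); target <- clean_sequence(target, lenient)
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("sw_align: sequences must be non-empty")
  if (nchar(query) > max_length || nchar(target) > max_length)
    stop(structure(
      class = c("pc_resource_error", "error", "condition"),
      list(message = paste0("sw_align: sequence length exceeds maximum of ",
                            max_length, " bases (alignment memory is quadratic",
                            " in the length)"),
           call = NULL)))
  res <- sw_align_cpp(query, target, scoring$match, scoring$mismatch, scoring$gap)
  structure(res, class = "pc_alignment")
}

#' @export
print.pc_alignment <- function(x, ...) {
  if (x$columns == 0L) {
    cat("<local alignment: empty (score 0)>\n")
  } else {
    cat(sprintf("<local alignment: score %d, query [%d,%d), target [%d,%d), %d/%d identical columns>\n",
                x$score, x$q_start, x$q_end, x$t_start, x$t_end, x$matches, x$columns))
  }
  invisible(x)
}

#' Does an alignment hit qualify as a detectable palindrome?
#'
#' Applies the five acceptance ratios of [filter_thresholds()] to a hit
#' produced by [sw_align()] between a read and its reverse complement.
#' Empty alignments (zero columns) always fail.
#'
#' @param hit A `pc_alignment`.
#' @param read_length Length of the read the hit was computed on.
#' @param thresholds A [filter_thresholds()].
#' @param scoring The [scoring_scheme()] used for the alignment (needed for
#'   the maximum-attainable-score ratio).
#' @return `TRUE` iff every threshold is met.
#' @export
passes_filters <- function(hit, read_length, thresholds = filter_thresholds(),
                           scoring = scoring_scheme()) {
  stopifnot(inherits(hit, "pc_alignment"), inherits(thresholds, "pc_filters"),
            inherits(scoring, "pc_scoring"))
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1L) stop("read_length must be >= 1")
  if (hit$columns == 0L) return(FALSE)
  score <- hit$score
  score >= thresholds$filter_factor * scoring$match * read_length &&
    (hit$q_end - hit$q_start) / read_length >= thresholds$query_coverage &&
    hit$matches / hit$columns >= thresholds$query_identity &&
    score / hit$columns >= thresholds$relative_score &&
    score / read_length >= thresholds$base_score
}
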