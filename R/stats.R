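#' Summarise a correction run
#'
#' Aggregates per-read correction records into read-set statistics: read
#' and length counts before and after correction, palindrome incidence
#' (a read counts as "with palindromes" iff at least one split was
#' performed), discard count, and the histogram of split iterations per
#' read. Average output length is the arithmetic mean over emitted reads
#' only; discarded fragments are counted but excluded from it.
#'
#' @param records List of `pc_correction` records (from [correct_set()] or
#'   [read_records()]).
#' @return An object of class `pc_summary` with fields `n_reads_in`,
#'   `mean_len_in`, `n_reads_with_palindromes`, `pct_with_palindromes`,
#'   `n_reads_out`, `mean_len_out`, `n_discarded`, `iteration_histogram`
#'   (named integer vector, iteration count -> number of reads).
#' @export
summarize_correction <- function(records) {
  stopifnot(is.list(records))
  if (length(records) == 0L) {
    return(structure(list(
      n_reads_in = 0L, mean_len_in = 0, n_reads_with_palindromes = 0L,
      pct_with_palindromes = 0, n_reads_out = 0L, mean_len_out = 0,
      n_discarded = 0L, iteration_histogram = integer(0)),
      class = "pc_summary"))
  }
  len_in <- vapply(records, function(r) as.numeric(r$input_length), numeric(1))
  iters <- vapply(records, function(r) as.integer(r$iterations), integer(1))
  frag_lens <- unlist(lapply(records, record_fragment_lengths))
  n_disc <- sum(vapply(records, record_n_discarded, integer(1)))
  hist <- table(iters)
  hist_v <- as.integer(hist); names(hist_v) <- names(hist)
  n_with <- sum(iters >= 1L)
  structure(list(
    n_reads_in = length(records),
    mean_len_in = mean(len_in),
    n_reads_with_palindromes = n_with,
    pct_with_palindromes = 100 * n_with / length(records),
    n_reads_out = length(frag_lens),
    mean_len_out = if (length(frag_lens) > 0L) mean(frag_lens) else 0,
    n_discarded = n_disc,
    iteration_histogram = hist_v),
    class = "pc_summary")
}

record_fragment_lengths <- function(r) {
  if (!is.null(r$fragment_lengths)) return(as.numeric(r$fragment_lengths))
  vapply(r$fragments, function(f) as.numeric(nchar(f$seq)), numeric(1))
}

record_n_discarded <- function(r) {
  if (!is.null(r$discarded_lengths)) return(length(r$discarded_lengths))
  length(r$discarded)
}

#' @export
print.pc_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<correction summary>\n",
    "  reads in:             %d (mean length %.1f b)\n",
    "  with palindromes:     %d (%.1f%%)\n",
    "  reads out:            %d (mean length %.1f b)\n",
    "  discarded (< min):    %d\n"),
    x$n_reads_in, x$mean_len_in, x$n_reads_with_palindromes,
    x$pct_with_palindromes, x$n_reads_out, x$mean_len_out, x$n_discarded))
  if (length(x$iteration_histogram) > 0L) {
    cat("  iterations histogram: ",
        paste(sprintf("%s:%d", names(x$iteration_histogram),
                      x$iteration_histogram), collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method plot pc_summary
plot.pc_summary <- function(x, ...) {
  h <- x$iteration_histogram
  if (length(h) == 0L) stop("empty summary: nothing to plot")
  graphics::barplot(h, xlab = "split iterations per read",
                    ylab = "number of reads", ...)
  invisible(x)
}

#' Per-read GC-content profile
#'
#' Computes the GC fraction of every read (`N` excluded from numerator and
#' denominator) and bins the values into a histogram over `[0,1]`
#' normalised to sum 1. Reads with no A/C/G/T at all are excluded with a
#' warning. Because splitting neither edits nor drops bases, the aggregate
#' base-level GC of a corrected read set without discards equals that of
#' its input.
#'
#' @param reads List of `pc_read`s.
#' @param n_bins Number of equal-width bins over `[0,1]`.
#' @return An object of class `pc_gc_profile`: list with `breaks`
#'   (length `n_bins + 1`), `density` (bin masses summing to 1), and `gc`
#'   (per-read fractions).
#' @export
gc_profile <- function(reads, n_bins = 20L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be >= 1")
  gc <- vapply(reads, function(r) {
    counts <- base_counts(r$seq)
    acgt <- sum(counts[c("A", "C", "G", "T")])
    if (acgt == 0) return(NA_real_)
    (counts[["G"]] + counts[["C"]]) / acgt
  }, numeric(1))
  if (anyNA(gc)) {
    warning(sum(is.na(gc)), " read(s) with no unambiguous bases excluded from GC profile")
    gc <- gc[!is.na(gc)]
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- if (length(gc) > 0L)
    tabulate(pmin(findInterval(gc, breaks, rightmost.closed = TRUE), n_bins),
             nbins = n_bins)
  else rep(0L, n_bins)
  density <- if (sum(counts) > 0L) counts / sum(counts) else rep(0, n_bins)
  structure(list(breaks = breaks, density = density, gc = gc),
            class = "pc_gc_profile")
}

base_counts <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  vapply(c(A = "A", C = "C", G = "G", T = "T", N = "N"),
         function(x) sum(b == x), numeric(1))
}

#' @export
#' @method plot pc_gc_profile
plot.pc_gc_profile <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mids, x$density, type = "h", lwd = 4,
                 xlab = "GC fraction", ylab = "density", xlim = c(0, 1), ...)
  invisible(x)
}

#' Write a correction summary report
#'
#' Emits both machine-readable forms of a [summarize_correction()] result:
#' `<stem>.json` and `<stem>.tsv`, with fields named exactly as in the
#' summary. Histogram keys are serialised in ascending iteration order.
#'
#' @param stats A `pc_summary`.
#' @param path Output stem; `.json` / `.tsv` suffixes are appended (an
#'   existing `.json` or `.tsv` suffix on `path` is treated as the stem).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_report <- function(stats, path) {
  stopifnot(inherits(stats, "pc_summary"))
  stem <- sub("\\.(json|tsv)$", "", path)
  h <- stats$iteration_histogram
  h <- h[order(as.integer(names(h)))]
  obj <- list(
    n_reads_in = stats$n_reads_in, mean_len_in = stats$mean_len_in,
    n_reads_with_palindromes = stats$n_reads_with_palindromes,
    pct_with_palindromes = stats$pct_with_palindromes,
    n_reads_out = stats$n_reads_out, mean_len_out = stats$mean_len_out,
    n_discarded = stats$n_discarded,
    iteration_histogram = as.list(stats::setNames(as.integer(h), names(h))))
  json_path <- paste0(stem, ".json"); tsv_path <- paste0(stem, ".tsv")
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  flat <- obj
  flat$iteration_histogram <- paste(sprintf("%s:%d", names(h), as.integer(h)),
                                    collapse = ",")
  utils::write.table(
    data.frame(field = names(flat),
               value = vapply(flat, function(v) as.character(v), character(1)),
               stringsAsFactors = FALSE),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Read a summary report back
#'
#' Parses the JSON form written by [write_report()] into a `pc_summary`.
#'
#' @param path Path to the `.json` report (or the stem).
#' @return A `pc_summary`.
#' @export
read_report <- function(path) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$iteration_histogram
  hv <- as.integer(unlist(h))
  if (length(hv) > 0L) names(hv) <- names(h) else hv <- integer(0)
  structure(list(
    n_reads_in = as.integer(obj$n_reads_in), mean_len_in = obj$mean_len_in,
    n_reads_with_palindromes = as.integer(obj$n_reads_with_palindromes),
    pct_with_palindromes = obj$pct_with_palindromes,
    n_reads_out = as.integer(obj$n_reads_out), mean_len_out = obj$mean_len_out,
    n_discarded = as.integer(obj$n_discarded), iteration_histogram = hv),
    class = "pc_summary")
}

#' Write per-read correction records
#'
#' One row per input read: id, input length, iteration count, fragment and
#' discarded-fragment lengths (comma-joined), and the split tree as
#' `start-end:pos` triples in original-read coordinates.
#'
#' @param records List of `pc_correction`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  df <- data.frame(
    read_id = vapply(records, function(r) r$input_id, character(1)),
    input_length = vapply(records, function(r) as.integer(r$input_length), integer(1)),
    iterations = vapply(records, function(r) as.integer(r$iterations), integer(1)),
    n_fragments = vapply(records, function(r) length(record_fragment_lengths(r)), integer(1)),
    n_discarded = vapply(records, record_n_discarded, integer(1)),
    fragment_lengths = vapply(records, function(r)
      paste(record_fragment_lengths(r), collapse = ","), character(1)),
    discarded_lengths = vapply(records, function(r) {
      if (!is.null(r$discarded_lengths)) paste(r$discarded_lengths, collapse = ",")
      else paste(vapply(r$discarded, function(f) nchar(f$seq), integer(1)), collapse = ",")
    }, character(1)),
    split_positions = vapply(records, function(r)
      paste(vapply(r$split_positions, function(s)
        sprintf("%d-%d:%d", s$interval[1], s$interval[2], s$pos), character(1)),
        collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-read correction records
#'
#' Parses a TSV written by [write_records()] into lightweight records
#' accepted by [summarize_correction()].
#'
#' @param path Records TSV path.
#' @return List of records with `input_id`, `input_length`, `iterations`,
#'   `fragment_lengths`, `discarded_lengths`, `split_positions`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  parse_num <- function(s) if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ",")[[1]])
  lapply(seq_len(nrow(df)), function(i) {
    sp <- df$split_positions[i]
    splits <- if (is.na(sp) || sp == "") list() else lapply(
      strsplit(sp, ",")[[1]], function(tok) {
        m <- regmatches(tok, regexec("^(\\d+)-(\\d+):(\\d+)$", tok))[[1]]
        if (length(m) != 4L) stop("malformed split record '", tok, "' in ", path)
        list(interval = c(as.integer(m[2]), as.integer(m[3])), pos = as.integer(m[4]))
      })
    list(input_id = df$read_id[i],
         input_length = as.integer(df$input_length[i]),
         iterations = as.integer(df$iterations[i]),
         fragment_lengths = parse_num(df$fragment_lengths[i]),
         discarded_lengths = parse_num(df$discarded_lengths[i]),
         split_positions = splits)
  })
}
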