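#' Correction parameters
#'
#' Bundles everything the recursive palindrome-splitting procedure needs:
#' the alignment scoring scheme, the hit-acceptance thresholds, the minimum
#' emitted fragment length (fragments below it are discarded, including
#' intact input reads), and a safety cap on split events per input read.
#'
#' @param min_len Minimum emitted fragment length in bases (default 50).
#' @param max_iterations Cap on split events per input read (default 64;
#'   real data rarely needs more than ~15).
#' @param scoring A [scoring_scheme()].
#' @param thresholds A [filter_thresholds()].
#' @param max_length Maximum read length the aligner accepts; longer reads
#'   are passed through uncorrected with a warning.
#' @return An object of class `pc_params`.
#' @export
correction_params <- function(min_len = 50L, max_iterations = 64L,
                              scoring = scoring_scheme(),
                              thresholds = filter_thresholds(),
                              max_length = 100000L) {
  min_len <- as.integer(min_len); max_iterations <- as.integer(max_iterations)
  if (is.na(min_len) || min_len < 1L) stop("min_len must be >= 1")
  if (is.na(max_iterations) || max_iterations < 1L) stop("max_iterations must be >= 1")
  stopifnot(inherits(scoring, "pc_scoring"), inherits(thresholds, "pc_filters"))
  structure(list(min_len = min_len, max_iterations = max_iterations,
                 scoring = scoring, thresholds = thresholds,
                 max_length = as.integer(max_length)),
            class = "pc_params")
}

#' Detect a palindromic junction in a read
#'
#' Aligns the read against its own reverse complement; if the best local
#' hit passes the acceptance filters, the split position is computed from
#' the two palindrome arms. The hit occupies `[q_start, q_end)` on the read
#' and `[t_start, t_end)` on the reverse complement; mapped back to read
#' coordinates the second arm is `[n - t_end, n - t_start)`. The split
#' point is the floor midpoint of the union of the two arm intervals:
#' `n/2` for a perfect palindrome, the junction for an embedded palindrome,
#' and the spacer midpoint for a separated inverted repeat.
#'
#' @param read A [new_read()].
#' @param params A [correction_params()].
#' @return The split position (integer, `0 < pos < n`), or `NULL` when no
#'   detectable palindrome is present. Reads shorter than 2 bases always
#'   return `NULL`.
#' @export
detect_split <- function(read, params = correction_params()) {
  stopifnot(inherits(read, "pc_read"), inherits(params, "pc_params"))
  n <- nchar(read$seq)
  if (n < 2L) return(NULL)
  if (n > params$max_length) {
    warning("read '", read$id, "' (", n, " b) exceeds the aligner maximum of ",
            params$max_length, " b; passed through uncorrected")
    return(NULL)
  }
  hit <- sw_align(read$seq, revcomp_cpp(read$seq), scoring = params$scoring,
                  max_length = params$max_length)
  if (!passes_filters(hit, n, params$thresholds, params$scoring)) return(NULL)
  arm1 <- c(hit$q_start, hit$q_end)
  arm2 <- c(n - hit$t_end, n - hit$t_start)
  pos <- (min(arm1[1], arm2[1]) + max(arm1[2], arm2[2])) %/% 2L
  if (pos <= 0L || pos >= n) return(NULL)  # degenerate guard: never split at an end
  as.integer(pos)
}

#' Split a read in two at a position
#'
#' Partitions sequence and quality at `pos`; fragment origins are the
#' corresponding sub-intervals of the parent's origin, and fragment ids are
#' derived with [fragment_id()] in original-read coordinates.
#'
#' @param read A [new_read()].
#' @param pos Split position, `0 < pos < length(read)`.
#' @return A list of two `pc_read`s whose concatenation equals the input.
#' @export
split_read <- function(read, pos) {
  stopifnot(inherits(read, "pc_read"))
  n <- nchar(read$seq)
  pos <- as.integer(pos)
  if (is.na(pos) || pos <= 0L || pos >= n)
    stop("split position must satisfy 0 < pos < ", n, " (got ", pos, ")")
  o <- read$origin
  mk <- function(s, e) {
    new_read(id = fragment_id(o$parent, o$start + s, o$start + e),
             seq = substr(read$seq, s + 1L, e),
             qual = if (is.null(read$qual)) NULL else substr(read$qual, s + 1L, e),
             origin = list(parent = o$parent, start = o$start + s, end = o$start + e))
  }
  list(mk(0L, pos), mk(pos, n))
}

#' Correct one read by recursive palindrome splitting
#'
#' Depth-first: detect a palindromic junction, split at its center, recurse
#' on both halves (left first) until no palindrome is detected or the
#' iteration cap is reached, at which point the remaining fragments are
#' emitted as-is with a warning. Fragments shorter than `min_len` —
#' including intact input reads — are routed to `discarded`. No base is
#' ever edited, added, or removed: emitted and discarded fragments tile the
#' input exactly.
#'
#' @param read A [new_read()] over `A,C,G,T,N`.
#' @param params A [correction_params()].
#' @return An object of class `pc_correction`: list with `input_id`,
#'   `input_length`, `fragments` (emitted reads, left-to-right in input
#'   coordinates), `discarded`, `iterations` (number of split events), and
#'   `split_positions` (list of `list(interval=c(start,end), pos=)` in
#'   original-read coordinates, recording the split tree).
#' @examples
#' x <- random_template(100, seed = 1)
#' r <- new_read("r1", paste0(x, reverse_complement(x)))
#' res <- correct_read(r)
#' res$iterations           # 1 split
#' length(res$fragments)    # 2 clean halves
#' @export
correct_read <- function(read, params = correction_params()) {
  stopifnot(inherits(read, "pc_read"), inherits(params, "pc_params"))
  fragments <- list(); discarded <- list()
  splits <- list(); iterations <- 0L
  capped <- FALSE

  emit <- function(r) {
    if (nchar(r$seq) >= params$min_len) fragments[[length(fragments) + 1L]] <<- r
    else discarded[[length(discarded) + 1L]] <<- r
  }
  recurse <- function(r) {
    pos <- if (iterations >= params$max_iterations) NULL else detect_split(r, params)
    if (iterations >= params$max_iterations && !capped) capped <<- TRUE
    if (is.null(pos)) { emit(r); return(invisible()) }
    iterations <<- iterations + 1L
    splits[[length(splits) + 1L]] <<- list(
      interval = c(r$origin$start, r$origin$end),
      pos = r$origin$start + pos)
    halves <- split_read(r, pos)
    recurse(halves[[1L]])
    recurse(halves[[2L]])
  }

  if (nchar(read$seq) > 0L) recurse(read) else discarded <- list(read)
  if (capped)
    warning("read '", read$id, "': reached max_iterations (",
            params$max_iterations, "); remaining fragments emitted as-is")
  structure(list(input_id = read$id, input_length = nchar(read$seq),
                 fragments = fragments, discarded = discarded,
                 iterations = iterations, split_positions = splits),
            class = "pc_correction")
}

#' @export
print.pc_correction <- function(x, ...) {
  cat(sprintf("<correction of %s (%d b): %d split%s -> %d emitted, %d discarded>\n",
              x$input_id, x$input_length, x$iterations,
              if (x$iterations == 1L) "" else "s",
              length(x$fragments), length(x$discarded)))
  invisible(x)
}

#' Correct a set of reads
#'
#' Applies [correct_read()] to every read in input order and collects all
#' emitted fragments plus the per-read correction records. Deterministic
#' given identical input and parameters.
#'
#' @param reads List of `pc_read`s (e.g. from [read_seqs()]).
#' @param params A [correction_params()].
#' @return An object of class `pc_correction_set`: list with `reads`
#'   (all emitted fragments, input order preserved) and `records` (one
#'   `pc_correction` per input read).
#' @export
correct_set <- function(reads, params = correction_params()) {
  stopifnot(is.list(reads))
  records <- lapply(reads, correct_read, params = params)
  out <- unlist(lapply(records, function(r) r$fragments), recursive = FALSE)
  if (is.null(out)) out <- list()
  structure(list(reads = out, records = records), class = "pc_correction_set")
}

#' @export
print.pc_correction_set <- function(x, ...) {
  nin <- length(x$records)
  nsplit <- sum(vapply(x$records, function(r) r$iterations > 0L, logical(1)))
  cat(sprintf("<correction set: %d reads in, %d with palindromes, %d fragments out>\n",
              nin, nsplit, length(x$reads)))
  invisible(x)
}

#' @export
#' @method summary pc_correction_set
summary.pc_correction_set <- function(object, ...) {
  summarize_correction(object$records)
}
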