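#' Long-read error model
#'
#' Per-base independent substitution, insertion (one random base after a
#' position), and deletion probabilities. The defaults (1% substitution,
#' 8% insertion, 3% deletion, ~12% total) emulate the indel-dominated
#' error profile of early single-molecule long reads; published
#' base-calling error rates for those technologies span roughly 11-38%.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities, each in
#'   `[0,1)`, with `sub_rate + del_rate < 1`.
#' @param seed Optional RNG seed; identical seeds give identical output.
#' @return An object of class `pc_error_model`.
#' @export
error_model <- function(sub_rate = 0.01, ins_rate = 0.08, del_rate = 0.03,
                        seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates >= 1))
    stop("error rates must each lie in [0,1)")
  if (sub_rate + del_rate >= 1)
    stop("sub_rate + del_rate must be < 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = seed),
            class = "pc_error_model")
}

#' Random DNA template
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, split evenly within each pair.
#'
#' @param length Template length in bases (>= 1).
#' @param gc Target GC fraction in `[0,1]`.
#' @param seed Optional RNG seed for reproducibility.
#' @return A DNA sequence string.
#' @examples
#' random_template(8, gc = 0, seed = 1)  # A/T only
#' @export
random_template <- function(length, gc = 0.5, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1")
  if (!is.finite(gc) || gc < 0 || gc > 1) stop("gc must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Fold a sequence back on itself
#'
#' Models the amplification artifact in which the polymerase, after
#' synthesising a prefix, re-elongates along the product it just created:
#' the result is `seq[1:breakpoint]` immediately followed by its own
#' reverse complement. Repeated full-length folds yield nested palindromes
#' with `2^k` copies of the original fragment.
#'
#' @param seq DNA sequence string.
#' @param breakpoint Fold point, `1 <= breakpoint <= nchar(seq)` (default:
#'   full length).
#' @return The folded sequence, length `2 * breakpoint`.
#' @examples
#' fold("AACC")     # "AACCGGTT"
#' fold("AACC", 2)  # "AATT"
#' @export
fold <- function(seq, breakpoint = nchar(seq)) {
  n <- nchar(seq)
  breakpoint <- as.integer(breakpoint)
  if (is.na(breakpoint) || breakpoint < 1L || breakpoint > n)
    stop("breakpoint must satisfy 1 <= breakpoint <= ", n)
  prefix <- substr(seq, 1L, breakpoint)
  paste0(prefix, reverse_complement(prefix))
}

#' Apply a sequencing error model to a sequence
#'
#' Each base is independently deleted (prob `del_rate`), substituted to a
#' different base (prob `sub_rate`), or kept; independently, a random base
#' is inserted after each position with prob `ins_rate`. Alongside the
#' mutated sequence a monotone coordinate map from pre-error to post-error
#' positions is returned, used to project true fold points through the
#' noise.
#'
#' @param seq DNA sequence string.
#' @param model An [error_model()]. If `model$seed` is set, the RNG is
#'   seeded before drawing.
#' @return List with `seq` (mutated sequence) and `map`, an integer vector
#'   of length `nchar(seq) + 1` mapping each 0-based pre-error boundary
#'   `b` to the post-error boundary `map[b + 1]`; `map[1] == 0` and the
#'   last entry equals the output length.
#' @export
apply_errors <- function(seq, model = error_model()) {
  stopifnot(inherits(model, "pc_error_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  n <- nchar(seq)
  if (n == 0L) return(list(seq = "", map = 0L))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  u <- stats::runif(n)
  del <- u < model$del_rate
  sub <- !del & u < model$del_rate + model$sub_rate
  ins <- stats::runif(n) < model$ins_rate

  acgt <- c("A", "C", "G", "T")
  if (any(sub))
    bases[sub] <- vapply(bases[sub], function(b)
      sample(setdiff(acgt, b), 1L), character(1), USE.NAMES = FALSE)
  pieces <- bases
  pieces[del] <- ""
  if (any(ins)) {
    insbase <- sample(acgt, n, replace = TRUE)
    pieces[ins] <- paste0(pieces[ins], insbase[ins])
  }
  map <- c(0L, cumsum(as.integer(!del) + as.integer(ins)))
  list(seq = paste(pieces, collapse = ""), map = map)
}

#' Simulate a read set with palindromic chimeras and ground truth
#'
#' Generates `n_reads` reads: exactly `round(n_reads * palindromic_fraction)`
#' are chimeric (the first reads in the set, so the assignment is
#' deterministic given the seed), built by `folds` successive full-length
#' folds of a fresh random template; the rest are plain error-laden
#' templates. Every read is paired with a ground-truth record carrying the
#' fold points and their projections through the error-model coordinate
#' map.
#'
#' @param n_reads Number of reads (>= 1).
#' @param palindromic_fraction Fraction of chimeric reads in `[0,1]`.
#' @param template_length Template length in bases.
#' @param folds Number of full-length fold events per chimeric read (>= 1).
#' @param model An [error_model()].
#' @param gc Template GC fraction.
#' @param seed RNG seed for the whole set (overrides `model$seed`).
#' @param id_prefix Prefix for read identifiers.
#' @return List with `reads` (list of `pc_read`) and `truths` (list of
#'   `pc_sim_truth`: `read_id`, `template_id`, `is_palindromic`,
#'   `fold_points`, `arm_intervals`, `true_splits_posterror`).
#' @examples
#' sim <- simulate_readset(4, 0.5, template_length = 100, seed = 1)
#' sum(vapply(sim$truths, function(t) t$is_palindromic, logical(1)))  # 2
#' @export
simulate_readset <- function(n_reads, palindromic_fraction = 0.5,
                             template_length = 500L, folds = 1L,
                             model = error_model(), gc = 0.5,
                             seed = model$seed, id_prefix = "sim") {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) stop("n_reads must be >= 1")
  if (palindromic_fraction < 0 || palindromic_fraction > 1)
    stop("palindromic_fraction must lie in [0,1]")
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 1L) stop("folds must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  model$seed <- NULL  # one seed for the whole set; reads draw from the stream

  n_pal <- as.integer(round(n_reads * palindromic_fraction))
  L <- as.integer(template_length)
  reads <- vector("list", n_reads)
  truths <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    tmpl <- random_template(L, gc = gc)
    pal <- i <= n_pal
    if (pal) {
      pre <- tmpl
      for (f in seq_len(folds)) pre <- fold(pre)
      fold_points <- as.integer(L * 2^(seq_len(folds) - 1L))
      boundaries <- L * seq_len(2L^folds - 1L)
      arms <- lapply(seq_len(2L^folds), function(k) c(L * (k - 1L), L * k))
    } else {
      pre <- tmpl
      fold_points <- integer(0)
      boundaries <- integer(0)
      arms <- list(c(0L, L))
    }
    err <- apply_errors(pre, model)
    id <- sprintf("%s_%04d", id_prefix, i)
    reads[[i]] <- new_read(id, err$seq)
    truths[[i]] <- structure(list(
      read_id = id, template_id = paste0(id, "_tmpl"),
      is_palindromic = pal, fold_points = fold_points,
      arm_intervals = arms,
      true_splits_posterror = unname(err$map[boundaries + 1L])),
      class = "pc_sim_truth")
  }
  list(reads = reads, truths = truths)
}

#' Write a simulation ground-truth table
#'
#' Tab-separated columns: `read_id`, `is_palindromic`, `fold_points`,
#' `true_splits_posterror` (the last two comma-joined).
#'
#' @param truths List of `pc_sim_truth` from [simulate_readset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truths, path) {
  df <- data.frame(
    read_id = vapply(truths, function(t) t$read_id, character(1)),
    is_palindromic = vapply(truths, function(t) t$is_palindromic, logical(1)),
    fold_points = vapply(truths, function(t)
      paste(t$fold_points, collapse = ","), character(1)),
    true_splits_posterror = vapply(truths, function(t)
      paste(t$true_splits_posterror, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score corrections against simulation ground truth
#'
#' Read-level detection treats a read as flagged iff at least one split was
#' performed; precision and recall compare the flag against
#' `is_palindromic`. Split-position recall counts a true (post-error) fold
#' point as recovered when some predicted split lies within the tolerance.
#'
#' @param results List of `pc_correction` records (from [correct_set()]).
#' @param truths List of `pc_sim_truth`, same reads in any order; ids must
#'   match one-to-one.
#' @param tolerance_frac Tolerance as a fraction of each read's length
#'   (default 0.02); ignored when `tolerance_bp` is given.
#' @param tolerance_bp Absolute tolerance in bases.
#' @return An object of class `pc_evaluation`: counts `tp`, `fp`, `fn`,
#'   `tn`, detection `precision` (NA when nothing is flagged), `recall`,
#'   `false_positive_rate`, and `split_recall` plus `mean_split_error`
#'   (bases) over palindromic reads.
#' @export
evaluate_correction <- function(results, truths, tolerance_frac = 0.02,
                                tolerance_bp = NULL) {
  rid <- vapply(results, function(r) r$input_id, character(1))
  tid <- vapply(truths, function(t) t$read_id, character(1))
  if (!setequal(rid, tid) || anyDuplicated(rid) || anyDuplicated(tid))
    stop("correction results and truths do not match one-to-one by read id")
  truths <- truths[match(rid, tid)]

  flagged <- vapply(results, function(r) r$iterations >= 1L, logical(1))
  pal <- vapply(truths, function(t) t$is_palindromic, logical(1))
  tp <- sum(flagged & pal); fp <- sum(flagged & !pal)
  fn <- sum(!flagged & pal); tn <- sum(!flagged & !pal)

  split_hits <- 0L; split_total <- 0L; errs <- numeric(0)
  for (i in seq_along(results)) {
    tr <- truths[[i]]
    if (!tr$is_palindromic || length(tr$true_splits_posterror) == 0L) next
    n <- results[[i]]$input_length
    tol <- if (!is.null(tolerance_bp)) tolerance_bp else tolerance_frac * n
    pred <- vapply(results[[i]]$split_positions, function(s) s$pos, numeric(1))
    for (ts in tr$true_splits_posterror) {
      split_total <- split_total + 1L
      if (length(pred) > 0L) {
        d <- min(abs(pred - ts))
        errs <- c(errs, d)
        if (d <= tol) split_hits <- split_hits + 1L
      }
    }
  }
  structure(list(
    n = length(results), tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    false_positive_rate = if (fp + tn > 0L) fp / (fp + tn) else NA_real_,
    split_recall = if (split_total > 0L) split_hits / split_total else NA_real_,
    mean_split_error = if (length(errs) > 0L) mean(errs) else NA_real_),
    class = "pc_evaluation")
}

#' @export
print.pc_evaluation <- function(x, ...) {
  cat(sprintf(paste0(
    "<evaluation of %d reads>\n",
    "  detection: precision %s, recall %s, FPR %s\n",
    "  splits: recall %s, mean |error| %s b\n"),
    x$n, fmt_ratio(x$precision), fmt_ratio(x$recall),
    fmt_ratio(x$false_positive_rate), fmt_ratio(x$split_recall),
    if (is.na(x$mean_split_error)) "n/a" else sprintf("%.1f", x$mean_split_error)))
  invisible(x)
}

fmt_ratio <- function(v) if (is.na(v)) "n/a" else sprintf("%.3f", v)
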