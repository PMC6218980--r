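# Naive full-matrix Smith-Waterman score, independent of the package's
# aligner: plain R dynamic programming, linear gaps, N never matches.
# Used as the ground-truth oracle for score equality checks.
sw_score_oracle <- function(a, b, match = 3, mismatch = -4, gap = -3) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  prev <- numeric(m + 1)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    s <- ifelse(bv == av[i] & av[i] != "N", match, mismatch)
    cand <- pmax(prev[1:m] + s, prev[2:(m + 1)] + gap, 0)
    for (j in seq_len(m)) {
      left <- cur[j] + gap
      cur[j + 1] <- if (left > cand[j]) left else cand[j]
    }
    rbest <- max(cur)
    if (rbest > best) best <- rbest
    prev <- cur
  }
  best
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Concatenate a correction's emitted + discarded fragments in input order.
tiled_sequence <- function(res) {
  frags <- c(res$fragments, res$discarded)
  if (length(frags) == 0L) return("")
  starts <- vapply(frags, function(f) f$origin$start, integer(1))
  paste(vapply(frags[order(starts)], function(f) f$seq, character(1)),
        collapse = "")
}

# Re-score an alignment path column by column under a scoring scheme.
rescore_path <- function(hit, scoring = scoring_scheme()) {
  if (hit$columns == 0L) return(0L)
  ops <- strsplit(hit$path, "", fixed = TRUE)[[1]]
  sum(ifelse(ops == "=", scoring$match,
             ifelse(ops == "X", scoring$mismatch, scoring$gap)))
}
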