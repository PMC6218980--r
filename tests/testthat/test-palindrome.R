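test_that("a perfect palindrome splits at its center", {
  x <- random_template(100, seed = 1)
  r <- new_read("r1", paste0(x, reverse_complement(x)))
  expect_identical(detect_split(r), 100L)
})

test_that("random non-palindromic reads are not split", {
  r <- new_read("r4", random_template(200, seed = 7))
  # the oracle confirms no self-vs-rc hit reaches the base-score bar
  expect_lt(sw_score_oracle(r$seq, reverse_complement(r$seq)), 200)
  expect_null(detect_split(r))
})

test_that("an embedded palindrome splits at the arm junction", {
  set.seed(3)
  B <- rand_seq(50); X <- rand_seq(75); C <- rand_seq(50)
  r <- new_read("r3", paste0(B, X, reverse_complement(X), C))
  pos <- detect_split(r)
  expect_false(is.null(pos))
  # junction at 125; chance matches at the block edges may extend the local
  # alignment by a column or two, shifting the union midpoint accordingly
  expect_lte(abs(pos - 125L), 2L)
})

test_that("reads shorter than two bases are never split", {
  expect_null(detect_split(new_read("tiny", "A")))
})

test_that("split_read partitions sequence, qualities, and provenance", {
  x <- random_template(200, seed = 5)
  q <- strrep("I", 200)
  r <- new_read("readA", x, qual = q)
  halves <- split_read(r, 100)
  expect_identical(paste0(halves[[1]]$seq, halves[[2]]$seq), x)
  expect_identical(nchar(halves[[1]]$qual), 100L)
  expect_identical(nchar(halves[[2]]$qual), 100L)
  expect_identical(halves[[1]]$id, "readA:0-100")
  expect_identical(halves[[2]]$id, "readA:100-200")
  expect_error(split_read(r, 0), "split position")
  expect_error(split_read(r, 200), "split position")

  # second-level split keeps original-read coordinates
  grand <- split_read(halves[[2]], 50)
  expect_identical(grand[[1]]$id, "readA:100-150")
  expect_identical(grand[[2]]$id, "readA:150-200")
})

test_that("a single fold is corrected with one split into two clean halves", {
  x <- random_template(100, seed = 2)
  r <- new_read("r1", paste0(x, reverse_complement(x)))
  res <- correct_read(r)
  expect_identical(res$iterations, 1L)
  expect_length(res$fragments, 2)
  expect_identical(vapply(res$fragments, function(f) nchar(f$seq), integer(1)),
                   c(100L, 100L))
  expect_identical(tiled_sequence(res), r$seq)
})

test_that("a double-folded read resolves into four fragments in three splits", {
  t <- random_template(150, seed = 42)
  r <- new_read("dbl", fold(fold(t)))
  expect_identical(nchar(r$seq), 600L)
  res <- correct_read(r)
  expect_identical(res$iterations, 3L)
  expect_length(res$fragments, 4)
  expect_length(res$discarded, 0)
  expect_identical(tiled_sequence(res), r$seq)
  expect_identical(res$iterations,
                   length(res$fragments) + length(res$discarded) - 1L)
})

test_that("fragments below the minimum length are discarded, not dropped", {
  x <- random_template(40, seed = 9)
  r <- new_read("short", paste0(x, reverse_complement(x)))
  res <- correct_read(r)  # default min_len 50
  expect_length(res$fragments, 0)
  expect_length(res$discarded, 2)
  expect_identical(vapply(res$discarded, function(f) nchar(f$seq), integer(1)),
                   c(40L, 40L))
  expect_identical(tiled_sequence(res), r$seq)

  # intact reads below min_len are discarded too
  res2 <- correct_read(new_read("tiny", random_template(30, seed = 10)))
  expect_length(res2$fragments, 0)
  expect_length(res2$discarded, 1)
})

test_that("the iteration cap stops recursion and emits remaining fragments", {
  t <- random_template(200, seed = 12)
  r <- new_read("deep", fold(fold(fold(t))))  # 8 arms, needs 7 splits
  params <- correction_params(max_iterations = 2)
  expect_warning(res <- correct_read(r, params), "max_iterations")
  expect_identical(res$iterations, 2L)
  expect_identical(tiled_sequence(res), r$seq)
})

test_that("correction conserves every base over a simulated mixed read set", {
  sim <- simulate_readset(40, 0.5, template_length = 300, folds = 1,
                          model = error_model(), seed = 77)
  for (r in sim$reads) {
    res <- correct_read(r)
    expect_identical(tiled_sequence(res), r$seq)
    for (f in res$fragments) expect_gte(nchar(f$seq), 50)
    for (f in res$discarded) expect_lt(nchar(f$seq), 50)
    expect_identical(res$iterations,
                     max(length(res$fragments) + length(res$discarded) - 1L, 0L))
  }
})

test_that("a read is flagged palindromic iff its reverse complement is", {
  set.seed(55)
  for (i in 1:8) {
    seq <- if (i %% 2 == 0) {
      x <- rand_seq(150); paste0(x, reverse_complement(x))
    } else rand_seq(300)
    a <- detect_split(new_read("f", seq))
    b <- detect_split(new_read("r", reverse_complement(seq)))
    expect_identical(is.null(a), is.null(b))
  }
})

test_that("correct_set preserves order, counts, and is idempotent", {
  x <- random_template(120, seed = 21)
  reads <- list(new_read("a", random_template(150, seed = 22)),
                new_read("b", paste0(x, reverse_complement(x))),
                new_read("c", random_template(150, seed = 23)))
  out <- correct_set(reads)
  expect_length(out$reads, 4)
  expect_identical(sum(vapply(out$records, function(r) r$iterations >= 1L,
                              logical(1))), 1L)
  expect_identical(out$records[[2]]$input_id, "b")

  # empty input
  empty <- correct_set(list())
  expect_length(empty$reads, 0)
  expect_length(empty$records, 0)

  # feeding the output back performs no further splits
  again <- correct_set(out$reads)
  expect_identical(sum(vapply(again$records, function(r) r$iterations,
                              integer(1))), 0L)
  expect_identical(vapply(again$reads, function(r) r$seq, character(1)),
                   vapply(out$reads, function(r) r$seq, character(1)))
})
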