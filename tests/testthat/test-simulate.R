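test_that("random templates honour the GC dial and the seed", {
  expect_false(grepl("[GC]", random_template(8, gc = 0, seed = 3)))
  expect_false(grepl("[AT]", random_template(8, gc = 1, seed = 3)))
  expect_identical(random_template(1000, seed = 1), random_template(1000, seed = 1))

  # observed GC within the binomial 99% CI of the target
  s <- random_template(1e4, gc = 0.36, seed = 2)
  gc_obs <- nchar(gsub("[AT]", "", s)) / 1e4
  expect_lt(abs(gc_obs - 0.36), 2.576 * sqrt(0.36 * 0.64 / 1e4))
})

test_that("folding concatenates a prefix with its reverse complement", {
  expect_identical(fold("AACC"), "AACCGGTT")
  expect_identical(fold("AACC", 2), "AATT")
  expect_error(fold("AACC", 0), "breakpoint")
  expect_error(fold("AACC", 5), "breakpoint")

  # any full-length fold is a perfect palindrome: equal to its own rc
  x <- random_template(150, seed = 4)
  f1 <- fold(x)
  expect_identical(nchar(f1), 300L)
  expect_identical(reverse_complement(f1), f1)

  # two full-length folds of a 150 b template: 600 b, four copies
  # alternating in orientation: x, rc(x), x, rc(x)
  f2 <- fold(f1)
  expect_identical(nchar(f2), 600L)
  expect_identical(substr(f2, 1, 150), x)
  expect_identical(substr(f2, 151, 300), reverse_complement(x))
  expect_identical(substr(f2, 301, 450), x)
  expect_identical(substr(f2, 451, 600), reverse_complement(x))
})

test_that("the error model respects its rates and coordinate map", {
  x <- random_template(500, seed = 6)
  clean <- apply_errors(x, error_model(0, 0, 0))
  expect_identical(clean$seq, x)
  expect_identical(clean$map, 0:500)

  set.seed(8)
  subbed <- apply_errors(x, error_model(sub_rate = 0.999, ins_rate = 0, del_rate = 0))
  expect_identical(nchar(subbed$seq), 500L)
  diff <- mapply(function(a, b) a != b,
                 strsplit(x, "")[[1]], strsplit(subbed$seq, "")[[1]])
  expect_gte(mean(diff), 0.99)

  # map is monotone non-decreasing and spans [0, output length]
  noisy <- apply_errors(x, error_model(seed = 9))
  expect_true(all(diff(noisy$map) >= 0))
  expect_identical(noisy$map[1], 0L)
  expect_identical(noisy$map[501], nchar(noisy$seq))

  # expected length n * (1 + ins - del); 50 replicates within 3 sigma
  set.seed(10)
  n <- 1e4
  lens <- replicate(50, nchar(apply_errors(random_template(n),
                                           error_model(0.01, 0.08, 0.03))$seq))
  per_base_var <- 0.97 * 0.03 + 0.08 * 0.92
  expect_lt(abs(mean(lens) - n * 1.05), 3 * sqrt(per_base_var * n / 50))
})

test_that("simulated read sets have the promised composition", {
  sim <- simulate_readset(10, 0.4, template_length = 200, seed = 1)
  pal <- vapply(sim$truths, function(t) t$is_palindromic, logical(1))
  expect_identical(sum(pal), 4L)
  expect_identical(vapply(sim$reads, function(r) r$id, character(1)),
                   vapply(sim$truths, function(t) t$read_id, character(1)))

  # no errors, one fold: palindromic reads are exactly twice the template
  clean <- simulate_readset(6, 0.5, template_length = 250, folds = 1,
                            model = error_model(0, 0, 0), seed = 2)
  lens <- vapply(clean$reads, function(r) nchar(r$seq), integer(1))
  expect_identical(lens[1:3], rep(500L, 3))
  expect_identical(lens[4:6], rep(250L, 3))
  t1 <- clean$truths[[1]]
  expect_identical(t1$fold_points, 250L)
  expect_identical(t1$true_splits_posterror, 250L)
  expect_length(t1$arm_intervals, 2)

  # same seed twice: byte-identical
  a <- simulate_readset(5, 0.5, template_length = 100, seed = 33)
  b <- simulate_readset(5, 0.5, template_length = 100, seed = 33)
  expect_identical(vapply(a$reads, `[[`, character(1), "seq"),
                   vapply(b$reads, `[[`, character(1), "seq"))

  # k full-length folds tile the pre-error read with 2^k arms
  deep <- simulate_readset(1, 1, template_length = 100, folds = 3,
                           model = error_model(0, 0, 0), seed = 3)
  tr <- deep$truths[[1]]
  expect_length(tr$arm_intervals, 8)
  ivs <- do.call(rbind, tr$arm_intervals)
  expect_identical(ivs[1, 1], 0L)
  expect_identical(ivs[8, 2], 800L)
  expect_identical(ivs[-1, 1], ivs[-8, 2])
})

test_that("evaluation scores detection and split placement against truth", {
  mk_res <- function(id, n, splits) {
    structure(list(input_id = id, input_length = n,
                   fragments = list(), discarded = list(),
                   iterations = length(splits),
                   split_positions = lapply(splits, function(p)
                     list(interval = c(0L, n), pos = p))),
              class = "pc_correction")
  }
  mk_truth <- function(id, pal, splits) {
    structure(list(read_id = id, template_id = id, is_palindromic = pal,
                   fold_points = splits, arm_intervals = list(),
                   true_splits_posterror = splits),
              class = "pc_sim_truth")
  }
  # perfect predictions
  ev <- evaluate_correction(list(mk_res("a", 200, 100), mk_res("b", 200, integer(0))),
                            list(mk_truth("a", TRUE, 100L), mk_truth("b", FALSE, integer(0))))
  expect_identical(ev$precision, 1)
  expect_identical(ev$recall, 1)
  expect_identical(ev$split_recall, 1)
  expect_identical(ev$false_positive_rate, 0)

  # nothing flagged: recall 0, precision undefined
  ev2 <- evaluate_correction(list(mk_res("a", 200, integer(0))),
                             list(mk_truth("a", TRUE, 100L)))
  expect_identical(ev2$recall, 0)
  expect_true(is.na(ev2$precision))

  # tolerance is a hard boundary
  at_tol <- evaluate_correction(list(mk_res("a", 200, 110)),
                                list(mk_truth("a", TRUE, 100L)),
                                tolerance_bp = 10)
  expect_identical(at_tol$split_recall, 1)
  past_tol <- evaluate_correction(list(mk_res("a", 200, 111)),
                                  list(mk_truth("a", TRUE, 100L)),
                                  tolerance_bp = 10)
  expect_identical(past_tol$split_recall, 0)

  # mismatched ids are an error
  expect_error(evaluate_correction(list(mk_res("a", 200, integer(0))),
                                   list(mk_truth("zz", TRUE, 100L))),
               "one-to-one")
})

test_that("ground-truth tables round trip through TSV", {
  sim <- simulate_readset(4, 0.5, template_length = 100, seed = 5)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truths, p)
  df <- read.table(p, sep = "\t", header = TRUE, colClasses = "character")
  expect_identical(nrow(df), 4L)
  expect_identical(df$read_id,
                   vapply(sim$truths, `[[`, character(1), "read_id"))
  expect_identical(as.integer(df$true_splits_posterror[1]),
                   sim$truths[[1]]$true_splits_posterror)
})
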