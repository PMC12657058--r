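test_that("smoothing is a masked centered moving average with edge shrink", {
  expect_identical(smooth_profile(c(3, 1, 4), window = 1), c(3, 1, 4))
  expect_equal(smooth_profile(rep(2, 10), window = 5), rep(2, 10))
  expect_equal(smooth_profile(c(1, 2, 3, 4, 5), window = 3),
               c(1.5, 2, 3, 4, 4.5))
  v <- c(1, NA, 3, 4)
  sm <- smooth_profile(v, window = 3)
  expect_true(is.na(sm[2]))         # masked stays masked
  expect_equal(sm[3], mean(c(3, 4)))  # masked neighbour excluded
  expect_error(smooth_profile(1:5, window = 4),
               class = "seqfrust_validation_error")
  expect_error(smooth_profile(1:5, window = -1),
               class = "seqfrust_validation_error")
})

test_that("normalization hits its contracts and preserves ranks", {
  v <- c(2, 4, 6, NA)
  mm <- normalize_profile(v, "minmax")
  expect_equal(mm, c(0, 0.5, 1, NA))
  z <- normalize_profile(c(rnorm(20), NA), "zscore")
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  set.seed(51)
  r <- rnorm(30)
  expect_identical(rank(normalize_profile(r, "zscore")), rank(r))
  expect_identical(rank(normalize_profile(r, "minmax")), rank(r))
  expect_error(normalize_profile(rep(1, 5), "zscore"),
               class = "seqfrust_stat_error")
})

test_that("correlation handles perfect association, ties and masking", {
  x <- c(1, 2, 3, 4, 5)
  up <- frustration_correlation(x, x * 2 + 1)
  expect_equal(up$rho, 1)
  down <- frustration_correlation(x, rev(x))
  expect_equal(down$rho, -1)
  # tied data against the explicit rank-then-Pearson oracle
  xt <- c(1, 2, 2, 3); yt <- c(10, 20, 30, 40)
  got <- frustration_correlation(xt, yt)
  rho_oracle <- cor(rank(xt), rank(yt))
  tstat <- rho_oracle * sqrt((4 - 2) / (1 - rho_oracle^2))
  p_oracle <- 2 * pt(-abs(tstat), df = 2)
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  expect_identical(got$n_pairs, 4L)
  # pairwise deletion: masked pairs never contribute
  xm <- c(x, NA, 99); ym <- c(x, 3, NA)
  expect_equal(frustration_correlation(xm, ym)$rho, 1)
  expect_error(frustration_correlation(1:2, 2:1),
               class = "seqfrust_stat_error")
  expect_error(frustration_correlation(rep(1, 5), 1:5),
               class = "seqfrust_stat_error")
})

test_that("correlation is symmetric and rank-invariant under monotone transforms", {
  set.seed(52)
  x <- rnorm(40); y <- x + rnorm(40)
  a <- frustration_correlation(x, y)
  b <- frustration_correlation(y, x)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  warped <- frustration_correlation(exp(x), y)
  expect_equal(warped$rho, a$rho, tolerance = 1e-12)
  pear <- frustration_correlation(x, y, method = "pearson")
  expect_equal(pear$rho, cor(x, y), tolerance = 1e-12)
  one <- frustration_correlation(x, y, alternative = "greater")
  expect_lt(one$p_value, a$p_value)
})

test_that("quartile labels follow the pinned percentile convention", {
  lab <- quartile_labels(1:8)
  expect_identical(lab, c("low", "low", rep("mid", 4), "high", "high"))
  expect_error(quartile_labels(rep(3, 10)), class = "seqfrust_stat_error")
  expect_error(quartile_labels(1:7), class = "seqfrust_stat_error")
  # brute-force percentile oracle on random continuous data
  set.seed(53)
  v <- rnorm(101)
  lab2 <- quartile_labels(v)
  q <- quantile(v, c(0.25, 0.75), type = 7)
  expect_identical(lab2 == "high", v > q[[2]])
  expect_identical(lab2 == "low", v < q[[1]])
  expect_equal(sum(lab2 == "high"), 25, tolerance = 1)
  expect_equal(sum(lab2 == "low"), 25, tolerance = 1)
  # masked positions stay unlabelled
  labm <- quartile_labels(c(v, NA))
  expect_true(is.na(labm[102]))
})

test_that("roc_pr is exact on separable and reversed scores", {
  labels <- c(rep("high", 4), rep("low", 4), rep("mid", 3))
  score <- c(10, 9, 8, 7, 1, 2, 3, 4, 100, -100, 5)  # mid ignored
  res <- roc_pr(score, labels, "high")
  expect_equal(res$auc_roc, 1)
  expect_equal(res$average_precision, 1)
  expect_equal(res$baseline, 0.5)
  rev <- roc_pr(-score, labels, "high")
  expect_equal(rev$auc_roc, 0)
  # the low task negates the score: separable the other way
  low <- roc_pr(score, labels, "low")
  expect_equal(low$auc_roc, 1)
  expect_error(roc_pr(score, rep("high", 11), "high"),
               class = "seqfrust_stat_error")
})

test_that("roc_pr AUC matches pROC and obeys the negation identity", {
  set.seed(54)
  labels <- sample(c("high", "low"), 60, replace = TRUE)
  score <- rnorm(60) + (labels == "high")
  res <- roc_pr(score, labels, "high")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels == "high", predictor = score, quiet = TRUE,
    direction = "<")))
  expect_equal(res$auc_roc, ref, tolerance = 1e-12)
  neg <- roc_pr(-score, labels, "high")
  expect_equal(neg$auc_roc, 1 - res$auc_roc, tolerance = 1e-12)
})

test_that("permutation null gives chance-level AUC and baseline-level AP", {
  set.seed(55)
  labels <- c(rep("high", 50), rep("low", 50))
  score <- rnorm(100)
  aucs <- numeric(200); aps <- numeric(200)
  for (b in 1:200) {
    perm <- sample(score)
    r <- roc_pr(perm, labels, "high")
    aucs[b] <- r$auc_roc
    aps[b] <- r$average_precision
  }
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
  expect_lt(abs(mean(aps) - 0.5), 0.05)
})

test_that("paired differences summarize elementwise coefficient gaps", {
  same <- paired_differences(c(0.3, 0.5), c(0.3, 0.5))
  expect_identical(same$differences, c(0, 0))
  shift <- paired_differences(c(0.4, 0.6, 0.8), c(0.3, 0.5, 0.7))
  expect_equal(shift$differences, rep(0.1, 3))
  set.seed(56)
  a <- runif(15); b <- runif(15)
  pd <- paired_differences(a, b)
  expect_equal(pd$median, sort(a - b)[8])
  expect_error(paired_differences(1:3, 1:2),
               class = "seqfrust_validation_error")
})

test_that("wilcoxon signed-rank test enumerates exactly for small n", {
  expect_equal(wilcoxon_greater(seq(0.6, 0.9, length.out = 10), 0.5),
               1 / 1024)
  # symmetric differences: p near one half
  sym <- 0.5 + c(-1, 1, -2, 2, -3, 3) / 10
  p_sym <- wilcoxon_greater(sym, 0.5)
  expect_lt(abs(p_sym - 0.5), 0.1)
  expect_error(wilcoxon_greater(c(0.6, 0.7, 0.8), 0.5),
               class = "seqfrust_stat_error")
  expect_error(wilcoxon_greater(rep(0.5, 10), 0.5),
               class = "seqfrust_stat_error")
  # large-sample path agrees with the exact one in direction
  set.seed(57)
  big <- 0.5 + abs(rnorm(30, 0.2, 0.05))
  expect_lt(wilcoxon_greater(big, 0.5), 0.001)
})

test_that("masked positions never change benchmark results", {
  set.seed(58)
  n <- 60
  score <- rnorm(n)
  bf <- score + rnorm(n, sd = 0.5)
  base <- benchmark_profile(score, bf)
  padded <- benchmark_profile(c(score, NA, 5), c(bf, 2, NA))
  for (f in c("rho", "p_value", "n_pairs", "auc_roc_high", "ap_high",
              "ap_low", "baseline_high"))
    expect_equal(padded[[f]], base[[f]], tolerance = 1e-12, label = f)
})

test_that("benchmark report has the documented fields and provenance config", {
  set.seed(59)
  score <- rnorm(40)
  bf <- score + rnorm(40)
  res <- benchmark_profile(score, bf, window = 5, normalize = "zscore")
  expect_s3_class(res, "benchmark_result")
  expect_true(all(c("rho", "p_value", "n_pairs", "auc_roc_high", "ap_high",
                    "ap_low", "baseline_high", "config") %in% names(res)))
  expect_identical(res$config$window, 5)
  expect_identical(res$config$normalize, "zscore")
  expect_true(res$rho >= -1 && res$rho <= 1)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})
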