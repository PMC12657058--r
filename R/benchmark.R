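# Benchmarking machinery: smoothing, normalization, rank correlation with
# significance, quartile ground-truth labelling, ROC/PR analysis, paired
# comparison of correlation coefficients, and the one-sided Wilcoxon
# signed-rank test against a chance baseline.
#
# All statistics treat masked (NA) positions by pairwise-complete deletion;
# adding a masked position never changes a result.

#' Centered moving average with masked positions
#'
#' Smooths a per-position signal over a centered window, averaging over
#' defined neighbours only; the window shrinks at the edges. Masked (NA)
#' positions stay masked. Used for plotting profiles; statistics default to
#' the raw signal.
#'
#' @param values Numeric vector, `NA` = masked.
#' @param window Odd positive integer window width (default 5).
#' @return Numeric vector of the same length.
#' @export
smooth_profile <- function(values, window = 5) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0)
    stop_validation("window must be an odd positive integer, got %s",
                    deparse(window))
  n <- length(values)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (is.na(values[k])) next
    lo <- max(1, k - half); hi <- min(n, k + half)
    out[k] <- mean(values[lo:hi], na.rm = TRUE)
  }
  out
}

#' Normalize a masked per-position signal
#'
#' `zscore` centers and scales to unit standard deviation over the defined
#' entries; `minmax` maps the defined range onto [0, 1]. Both are strictly
#' monotone, so rank-based statistics are unaffected.
#'
#' @param values Numeric vector, `NA` = masked.
#' @param method `"zscore"` or `"minmax"`.
#' @return Numeric vector of the same length, masked positions unchanged.
#' @export
normalize_profile <- function(values, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  if (sum(ok) < 2) stop_stat("need >= 2 defined values to normalize")
  v <- values[ok]
  if (max(v) == min(v)) stop_stat("zero spread: cannot normalize")
  out <- values
  out[ok] <- if (method == "zscore") (v - mean(v)) / stats::sd(v)
             else (v - min(v)) / (max(v) - min(v))
  out
}

#' Correlation between two masked signals
#'
#' Spearman (Pearson on average ranks, ties averaged) or Pearson
#' correlation after pairwise deletion of masked entries. The Spearman
#' p-value uses the large-sample t-approximation with n - 2 degrees of
#' freedom (two-sided by default; one-sided "greater" available); an exact
#' permutation p-value is available for n <= 10 without ties.
#'
#' @param x,y Numeric vectors of equal length, `NA` = masked.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alternative `"two.sided"` or `"greater"`.
#' @param exact Exact permutation p-value (Spearman, n <= 10 only).
#' @return List with `rho`, `p_value`, `n_pairs`.
#' @export
frustration_correlation <- function(x, y,
                                    method = c("spearman", "pearson"),
                                    alternative = c("two.sided", "greater"),
                                    exact = FALSE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(x) != length(y))
    stop_validation("x and y must have equal length (%d vs %d)",
                    length(x), length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3)
    stop_stat("need >= 3 jointly defined positions, have %d", sum(ok))
  xs <- x[ok]; ys <- y[ok]
  if (min(xs) == max(xs) || min(ys) == max(ys))
    stop_stat("degenerate input: all values tied")
  if (exact && method == "spearman" && sum(ok) > 10)
    stop_stat("exact permutation p-value supported only for n <= 10")
  use_exact <- exact && method == "spearman"
  ct <- suppressWarnings(
    stats::cor.test(xs, ys, method = method, alternative = alternative,
                    exact = if (method == "spearman") use_exact else NULL))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_pairs = sum(ok))
}

#' Quartile ground-truth labels from B-factors
#'
#' Residues strictly above the 75th percentile of the defined values are
#' labelled `"high"`, strictly below the 25th percentile `"low"`, the rest
#' `"mid"`; masked positions stay unlabelled (`NA`). Percentiles use the
#' linear-interpolation empirical convention (R type 7).
#'
#' @param bfactors Numeric vector, `NA` = masked.
#' @return Character vector of labels (`NA` where masked).
#' @export
quartile_labels <- function(bfactors) {
  ok <- !is.na(bfactors)
  if (sum(ok) < 8)
    stop_stat("need >= 8 defined values for stable quartiles, have %d",
              sum(ok))
  v <- bfactors[ok]
  if (min(v) == max(v)) stop_stat("degenerate spread: all values equal")
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  lab <- rep(NA_character_, length(bfactors))
  lab[ok] <- "mid"
  lab[ok & bfactors > q[2]] <- "high"
  lab[ok & bfactors < q[1]] <- "low"
  lab
}

# Rank-based AUC; identical to the trapezoid over the full empirical ROC
# sweep, with tied scores handled by average ranks.
auc_rank <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# Average precision as precision-weighted recall increments over distinct
# descending thresholds (ties grouped).
average_precision <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; pos <- positive[ord]
  np <- sum(pos)
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(pos)[grp_end]
  fp <- cumsum(!pos)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' ROC and precision-recall analysis of a frustration score
#'
#' Evaluates how well a continuous score classifies quartile-labelled
#' residues. Evaluation is restricted to the union of high- and low-label
#' residues (mid excluded), which makes the chance baseline for precision
#' the positive prevalence in that set (0.5 for clean quartiles). For
#' `target = "high"` positives are the high-label residues and the score is
#' used as-is (higher score predicts high B); for `target = "low"` the
#' positives are low-label residues and the score is negated.
#'
#' @param score Numeric vector, `NA` = masked.
#' @param labels Character labels from [quartile_labels()].
#' @param target `"high"` or `"low"`.
#' @return List with `auc_roc`, `average_precision`, `baseline` (positive
#'   prevalence), `n_pos`, `n_neg`.
#' @export
roc_pr <- function(score, labels, target = c("high", "low")) {
  target <- match.arg(target)
  if (length(score) != length(labels))
    stop_validation("score and labels must have equal length")
  use <- !is.na(score) & !is.na(labels) & labels %in% c("high", "low")
  s <- score[use]; lab <- labels[use]
  positive <- lab == target
  if (target == "low") s <- -s
  if (!any(positive) || all(positive))
    stop_stat("need both classes after quartile restriction (have %d positives of %d)",
              sum(positive), length(positive))
  list(auc_roc = auc_rank(s, positive),
       average_precision = average_precision(s, positive),
       baseline = mean(positive),
       n_pos = sum(positive), n_neg = sum(!positive))
}

#' Paired differences of correlation coefficients
#'
#' Elementwise sequence-based minus structure-based coefficients across a
#' set of protein/structure pairings; positive values mean the
#' sequence-based score tracks B-factor more strongly.
#'
#' @param rho_seq,rho_struct Numeric vectors of equal length.
#' @return List with `differences`, `median`, `mean`.
#' @export
paired_differences <- function(rho_seq, rho_struct) {
  if (length(rho_seq) != length(rho_struct))
    stop_validation("coefficient vectors must have equal length (%d vs %d)",
                    length(rho_seq), length(rho_struct))
  d <- rho_seq - rho_struct
  list(differences = d, median = stats::median(d), mean = mean(d))
}

#' One-sided Wilcoxon signed-rank test against a baseline
#'
#' Tests whether `values` are shifted above `baseline`. Zero differences
#' are dropped; with <= 15 nonzero differences the p-value is computed by
#' exact enumeration of all sign patterns (handles ties in the absolute
#' differences exactly), above that by the normal approximation with
#' continuity correction and tie handling.
#'
#' @param values Numeric vector.
#' @param baseline Scalar chance level.
#' @return One-sided (greater) p-value.
#' @export
wilcoxon_greater <- function(values, baseline) {
  d <- values - baseline
  d <- d[d != 0]
  if (!length(d)) stop_stat("all differences are zero")
  if (length(d) < 5)
    stop_stat("need >= 5 nonzero differences, have %d", length(d))
  m <- length(d)
  if (m <= 15) {
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    w_all <- as.numeric(signs %*% r)
    mean(w_all >= w_obs)
  } else {
    suppressWarnings(
      stats::wilcox.test(d, mu = 0, alternative = "greater",
                         exact = FALSE, correct = TRUE))$p.value
  }
}

#' Full benchmark of a frustration profile against B-factors
#'
#' Runs the evaluation used per protein: Spearman (or Pearson) correlation
#' of the score with per-residue B-factor, quartile labelling of the
#' B-factors, and ROC/PR classification of high- and low-B residues.
#' Higher frustration predicts higher B-factor; the low-B task uses the
#' negated score.
#'
#' @param score Frustration values (`NA` = masked).
#' @param bfactor Per-residue B-factors (`NA` = masked).
#' @param method Correlation method.
#' @param window Smoothing window applied to both signals before analysis;
#'   1 (default) = raw signal.
#' @param normalize Optional normalization (`"none"`, `"zscore"`,
#'   `"minmax"`) applied to both signals; affects only reported values,
#'   not ranks.
#' @return A `benchmark_result`: list with `rho`, `p_value`, `n_pairs`,
#'   `auc_roc_high`, `ap_high`, `ap_low`, `baseline_high`, `config`.
#' @export
benchmark_profile <- function(score, bfactor,
                              method = c("spearman", "pearson"),
                              window = 1, normalize = "none") {
  method <- match.arg(method)
  if (length(score) != length(bfactor))
    stop_validation("score and bfactor must have equal length (%d vs %d)",
                    length(score), length(bfactor))
  if (window > 1) {
    score <- smooth_profile(score, window)
    bfactor <- smooth_profile(bfactor, window)
  }
  if (normalize != "none") {
    score <- normalize_profile(score, normalize)
    bfactor <- normalize_profile(bfactor, normalize)
  }
  corr <- frustration_correlation(score, bfactor, method = method)
  joint <- ifelse(is.na(score), NA, bfactor)
  labs <- quartile_labels(joint)
  high <- roc_pr(score, labs, "high")
  low <- roc_pr(score, labs, "low")
  structure(list(rho = corr$rho, p_value = corr$p_value,
                 n_pairs = corr$n_pairs,
                 auc_roc_high = high$auc_roc, ap_high = high$average_precision,
                 ap_low = low$average_precision,
                 baseline_high = high$baseline,
                 n_masked_score = sum(is.na(score)),
                 n_masked_bfactor = sum(is.na(bfactor)),
                 config = list(method = method, window = window,
                               normalize = normalize,
                               baseline_convention = "high-low restricted")),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: rho = %.3f (p = %.3g, n = %d)\n",
              x$rho, x$p_value, x$n_pairs))
  cat(sprintf("  high-B: AUC = %.3f, AP = %.3f (baseline %.2f); low-B AP = %.3f\n",
              x$auc_roc_high, x$ap_high, x$baseline_high, x$ap_low))
  invisible(x)
}
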