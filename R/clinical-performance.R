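# Two-cutoff classification and clinical performance summaries.
#
# Calls: negative below the lower cutoff, positive above the upper,
# intermediate otherwise; values exactly on a cutoff are classed
# intermediate (the conservative convention: a boundary result defers to
# confirmatory testing). Sensitivity, specificity and accuracy are
# computed among the non-intermediate calls only, alongside the
# intermediate fraction, all with Wilson score intervals.

#' Classify concentrations with a two-cutoff rule
#'
#' @param values concentrations (pg/mL, finite)
#' @param lower,upper cutoffs with `0 < lower <= upper`
#' @return factor with levels `negative`, `intermediate`, `positive`
#' @examples
#' classify_two_cutoff(c(0.03, 0.05, 0.10), 0.04, 0.09)
#' @export
classify_two_cutoff <- function(values, lower, upper) {
  assert_scalar_number(lower, "lower", lower = 0, strict_lower = TRUE)
  assert_scalar_number(upper, "upper", lower = lower)
  if (any(!is.finite(values)))
    abort_invalid("values", "all values must be finite")
  cls <- ifelse(values < lower, "negative",
                ifelse(values > upper, "positive", "intermediate"))
  factor(cls, levels = c("negative", "intermediate", "positive"))
}

#' Performance summary of a classified cohort
#'
#' Confusion counts exclude intermediates: TP are amyloid-positive records
#' called positive, FN amyloid-positive called negative, etc. Sensitivity
#' = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/(TP+TN+FP+FN) (the "agreement excluding intermediates"
#' convention), each with a 95% Wilson interval, plus the intermediate
#' fraction over all n and the Mann-Whitney AUC of the raw values.
#'
#' @param values concentrations (pg/mL)
#' @param truth 0/1 amyloid status
#' @param lower,upper the two cutoffs
#' @param conf confidence level (default 0.95)
#' @return object of class `performance_summary` (a list): counts `tp`,
#'   `tn`, `fp`, `fn`, `n`, `n_intermediate`; `sensitivity`,
#'   `specificity`, `accuracy`, `intermediate_fraction` (each a
#'   `wilson_ci()` list); `auc` (list with `estimate`, `lower`, `upper`)
#' @export
performance_summary <- function(values, truth, lower, upper, conf = 0.95) {
  if (length(values) != length(truth))
    abort_invalid("truth", "length mismatch with values")
  if (!all(truth %in% c(0, 1)))
    abort_invalid("truth", "must be 0/1")
  cls <- classify_two_cutoff(values, lower, upper)
  n <- length(values)
  keep <- cls != "intermediate"
  tp <- sum(cls == "positive" & truth == 1)
  fn <- sum(cls == "negative" & truth == 1)
  tn <- sum(cls == "negative" & truth == 0)
  fp <- sum(cls == "positive" & truth == 0)

  metric <- function(x, m) {
    if (m == 0) {
      warning("metric undefined: empty non-intermediate stratum",
              call. = FALSE)
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    wilson_ci(x, m, conf)
  }
  auc <- if (length(unique(truth)) == 2)
    auc_mann_whitney(values, truth, conf)
  else list(estimate = NA_real_, lower = NA_real_, upper = NA_real_)

  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn, n = n,
    n_intermediate = sum(!keep),
    sensitivity = metric(tp, tp + fn),
    specificity = metric(tn, tn + fp),
    accuracy = metric(tp + tn, tp + tn + fp + fn),
    intermediate_fraction = wilson_ci(sum(!keep), n, conf),
    auc = auc), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  fmt <- function(ci) sprintf("%.1f%% (%.1f-%.1f%%)", 100 * ci$estimate,
                              100 * ci$lower, 100 * ci$upper)
  cat(sprintf("n = %d (TP %d, FN %d, TN %d, FP %d, intermediate %d)\n",
              x$n, x$tp, x$fn, x$tn, x$fp, x$n_intermediate))
  cat("sensitivity*:", fmt(x$sensitivity), "\n")
  cat("specificity*:", fmt(x$specificity), "\n")
  cat("accuracy*   :", fmt(x$accuracy), "\n")
  cat("intermediate:", fmt(x$intermediate_fraction), "\n")
  cat(sprintf("AUC         : %.2f (%.2f-%.2f)\n", x$auc$estimate,
              x$auc$lower, x$auc$upper))
  cat("* excluding samples in the intermediate zone\n")
  invisible(x)
}

#' Predictive values at a given prevalence
#'
#' `PPV = sens p / (sens p + (1 - spec)(1 - p))` and
#' `NPV = spec (1 - p) / ((1 - sens) p + spec (1 - p))`.
#'
#' @param sens,spec sensitivity and specificity, fractions in `[0, 1]`
#' @param prevalence disease prevalence p in `[0, 1]`
#' @return list with `ppv`, `npv` (fractions; `NaN` flagged on degenerate
#'   denominators)
#' @examples
#' predictive_values(0.903, 0.913, 0.5)
#' @export
predictive_values <- function(sens, spec, prevalence) {
  assert_scalar_number(sens, "sens", lower = 0, upper = 1)
  assert_scalar_number(spec, "spec", lower = 0, upper = 1)
  assert_scalar_number(prevalence, "prevalence", lower = 0, upper = 1)
  p <- prevalence
  ppv_den <- sens * p + (1 - spec) * (1 - p)
  npv_den <- (1 - sens) * p + spec * (1 - p)
  ppv <- if (ppv_den == 0) { if (p == 1) 1 else NaN } else sens * p / ppv_den
  npv <- if (npv_den == 0) { if (p == 0) 1 else NaN } else
    spec * (1 - p) / npv_den
  if (is.nan(ppv) || is.nan(npv))
    warning("degenerate predictive-value denominator", call. = FALSE)
  list(ppv = ppv, npv = npv)
}

#' PPV/NPV across a prevalence grid
#'
#' @param sens,spec sensitivity and specificity
#' @param grid prevalence values in (0, 1)
#' @return data.frame with `prevalence`, `ppv`, `npv`; PPV is
#'   non-decreasing and NPV non-increasing in prevalence by construction
#' @export
prevalence_sweep <- function(sens, spec,
                             grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(grid <= 0) || any(grid >= 1))
    abort_invalid("grid", "prevalences must lie strictly in (0, 1)")
  out <- t(vapply(grid, function(p) {
    pv <- predictive_values(sens, spec, p)
    c(pv$ppv, pv$npv)
  }, numeric(2)))
  data.frame(prevalence = grid, ppv = out[, 1], npv = out[, 2])
}

#' Mann-Whitney AUC with a DeLong confidence interval
#'
#' AUC is the fraction of (positive, negative) pairs where the positive
#' value exceeds the negative, ties counting one half. The CI is the
#' asymptotic normal interval with the DeLong placement variance, clipped
#' to `[0, 1]`.
#'
#' @param values marker values
#' @param truth 0/1 class labels (1 = diseased)
#' @param conf confidence level (default 0.95)
#' @return list with `estimate`, `lower`, `upper`, `se`
#' @export
auc_mann_whitney <- function(values, truth, conf = 0.95) {
  if (!all(truth %in% c(0, 1))) abort_invalid("truth", "must be 0/1")
  x <- values[truth == 1]   # positives
  y <- values[truth == 0]   # negatives
  if (!length(x) || !length(y))
    abort_invalid("truth", "both classes must be non-empty")
  m <- length(x); n <- length(y)
  # placements via midranks: O((m+n) log(m+n))
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n          # per-positive placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m  # per-negative placements
  auc <- mean(v10)
  se <- if (m > 1 && n > 1)
    sqrt(stats::var(v10) / m + stats::var(v01) / n) else NA_real_
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = auc,
       lower = if (is.na(se)) NA_real_ else max(0, auc - z * se),
       upper = if (is.na(se)) NA_real_ else min(1, auc + z * se),
       se = se)
}

#' Fold difference of group medians
#'
#' @param pos_values,neg_values concentrations for the two groups
#' @param digits decimals in the reported ratio (default 2)
#' @return `median(pos) / median(neg)`, rounded
#' @examples
#' median_fold_difference(0.132, 0.046)  # 2.87
#' @export
median_fold_difference <- function(pos_values, neg_values, digits = 2) {
  if (!length(pos_values) || !length(neg_values))
    abort_invalid("pos_values", "both groups must be non-empty")
  mn <- stats::median(neg_values)
  if (mn <= 0) abort_invalid("neg_values", "negative-group median must be > 0")
  round(stats::median(pos_values) / mn, digits)
}

#' Positivity rate with Wilson interval
#'
#' @param pos_count positives
#' @param n total (>= 1)
#' @param conf confidence level
#' @return `wilson_ci()` list
#' @examples
#' positivity_rate(495, 873)  # 56.7%
#' @export
positivity_rate <- function(pos_count, n, conf = 0.95) {
  wilson_ci(pos_count, n, conf)
}

#' Likelihood-ratio (G) test of homogeneity of proportions
#'
#' Tests whether the positivity proportion is equal across groups:
#' `G = 2 * sum O log(O/E)` over the groups-by-outcome table, df =
#' groups - 1, chi-square reference.
#'
#' @param group_counts data.frame with columns `positives` and `n`
#'   (one row per group), or a 2-column matrix
#' @return list with `statistic`, `df`, `p_value`
#' @export
homogeneity_test <- function(group_counts) {
  if (is.matrix(group_counts))
    group_counts <- data.frame(positives = group_counts[, 1],
                               n = group_counts[, 2])
  if (!all(c("positives", "n") %in% names(group_counts)))
    abort_invalid("group_counts", "needs columns positives, n")
  k <- nrow(group_counts)
  if (k < 2) abort_invalid("group_counts", "need >= 2 groups")
  if (any(group_counts$n < 1)) abort_invalid("group_counts", "all n must be >= 1")
  if (any(group_counts$positives < 0 |
          group_counts$positives > group_counts$n))
    abort_invalid("group_counts", "positives must lie in [0, n]")
  obs <- cbind(group_counts$positives, group_counts$n - group_counts$positives)
  p_hat <- sum(obs[, 1]) / sum(group_counts$n)
  expected <- cbind(group_counts$n * p_hat, group_counts$n * (1 - p_hat))
  terms <- obs * log(obs / expected)
  terms[obs == 0] <- 0  # 0 * log(0) -> 0
  g <- 2 * sum(terms)
  df <- k - 1
  list(statistic = g, df = df,
       p_value = stats::pchisq(g, df, lower.tail = FALSE))
}
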