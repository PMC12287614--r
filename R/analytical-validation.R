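# Analytical validation computations: EP05-style precision variance
# components, linearity across admixtures, dilution recovery, interference
# percent differences, stability, and cross-reactivity.

#' Nested variance components per sample (repeatability / within-lab)
#'
#' ANOVA method-of-moments decomposition of a replicate panel into
#' between-day, run-within-day and residual components, per sample.
#' Instrument (and analyst) levels, when present, are folded into the day
#' stratum: a "day" is a distinct instrument x day combination, so the
#' between-day component absorbs instrument-to-instrument differences,
#' which is what a within-laboratory precision claim needs. Negative
#' moment estimates are clamped to zero. Repeatability is the residual SD;
#' within-laboratory SD is the square root of the summed components.
#'
#' Unbalanced designs are handled with Searle's expected-mean-square
#' coefficients; for balanced designs these reduce to the familiar
#' n and n*R multipliers.
#'
#' @param table data.frame with columns `sample_id`, `day`, `run`,
#'   `conc_pg_ml` and optionally `instrument`
#' @return data.frame, one row per sample: `sample_id`, `mean_pg_ml`,
#'   `repeatability_sd`, `repeatability_cv_pct`, `within_lab_sd`,
#'   `within_lab_cv_pct`, `day_sd`, `run_sd`
#' @export
variance_components <- function(table) {
  need <- c("sample_id", "day", "run", "conc_pg_ml")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    abort_invalid("table", paste("needs columns", paste(need, collapse = ", ")))
  day_key <- if ("instrument" %in% names(table))
    interaction(table$instrument, table$day, drop = TRUE)
  else factor(table$day)
  out <- lapply(split(seq_len(nrow(table)), table$sample_id), function(idx) {
    y <- table$conc_pg_ml[idx]
    d <- droplevels(factor(day_key[idx]))
    r <- droplevels(interaction(d, table$run[idx], drop = TRUE))
    if (nlevels(r) < 2)
      stop("within-lab precision undefined: need >= 2 runs", call. = FALSE)
    if (any(tapply(y, r, length) < 2))
      stop("need >= 2 replicates per run", call. = FALSE)
    vc <- nested_moments(y, d, r)
    m <- mean(y)
    data.frame(
      sample_id = table$sample_id[idx][1],
      mean_pg_ml = m,
      repeatability_sd = sqrt(vc["residual"]),
      repeatability_cv_pct = 100 * sqrt(vc["residual"]) / m,
      within_lab_sd = sqrt(sum(vc)),
      within_lab_cv_pct = 100 * sqrt(sum(vc)) / m,
      day_sd = sqrt(vc["day"]),
      run_sd = sqrt(vc["run"]),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Method-of-moments nested decomposition y ~ day / run
#' @noRd
nested_moments <- function(y, day, run) {
  N <- length(y)
  ybar <- mean(y)
  day_code <- as.integer(day)                 # positional level codes
  run_code <- as.integer(run)
  run_means <- as.numeric(tapply(y, run, mean))
  run_n <- as.numeric(tapply(y, run, length))
  day_of_run <- as.integer(tapply(day_code, run, `[`, 1L))
  day_means <- as.numeric(tapply(y, day, mean))
  day_n <- as.numeric(tapply(y, day, length))
  D <- nlevels(day); R <- nlevels(run)

  ss_e <- sum((y - run_means[run_code])^2)
  ss_r <- sum(run_n * (run_means - day_means[day_of_run])^2)
  ss_d <- sum(day_n * (day_means - ybar)^2)
  df_e <- N - R
  df_r <- R - D
  df_d <- D - 1

  ms_e <- if (df_e > 0) ss_e / df_e else 0
  ms_r <- if (df_r > 0) ss_r / df_r else NA_real_
  ms_d <- if (df_d > 0) ss_d / df_d else NA_real_

  # Searle EMS coefficients for the unbalanced nested layout
  n_dr2_over_nd <- sum(run_n^2 / day_n[day_of_run])
  c1 <- if (df_r > 0) (N - n_dr2_over_nd) / df_r else NA_real_
  c2 <- if (df_d > 0) (n_dr2_over_nd - sum(run_n^2) / N) / df_d else NA_real_
  c3 <- if (df_d > 0) (N - sum(day_n^2) / N) / df_d else NA_real_

  v_e <- ms_e
  v_r <- if (!is.na(ms_r) && !is.na(c1) && c1 > 0) max(0, (ms_r - ms_e) / c1) else 0
  v_d <- if (!is.na(ms_d) && !is.na(c3) && c3 > 0)
    max(0, (ms_d - ms_e - c2 * v_r) / c3) else 0
  c(day = v_d, run = v_r, residual = v_e)
}

#' Default admixture ratio series (high:low)
#' @return numeric vector from 1 down to 0
#' @export
admixture_ratios <- function() {
  c(1, 0.875, 0.75, 0.625, 0.5, 0.375, 0.25, 0.125, 0.0625, 0)
}

#' Linearity across high:low admixtures
#'
#' Expected concentration at mixing ratio r is the affine interpolation
#' `r * high + (1 - r) * low` between the measured endpoint pools.
#' Per-level percent bias, average signed and absolute bias, the linear
#' regression of measured on expected, and nested F-tests of 2nd and
#' 3rd-order polynomial terms against the linear fit are returned.
#'
#' @param series data.frame with columns `ratio` and `conc_pg_ml`
#'   (replicate rows per ratio; >= 3 replicates per level recommended)
#' @param high,low measured endpoint pool concentrations; default to the
#'   mean measurements at `ratio == 1` and `ratio == 0`
#' @param alpha significance level for the polynomial comparison
#' @return list: `per_level` (ratio, expected, mean measured, bias_pct),
#'   `avg_signed_bias_pct`, `avg_abs_bias_pct`, `regression` (slope,
#'   intercept, r_squared), `poly_p` (p-values of the quadratic and cubic
#'   augmentations), `poly_improves` (logical)
#' @export
linearity_assess <- function(series, high = NULL, low = NULL, alpha = 0.05) {
  if (!is.data.frame(series) ||
      !all(c("ratio", "conc_pg_ml") %in% names(series)))
    abort_invalid("series", "needs columns ratio, conc_pg_ml")
  if (is.null(high)) {
    if (!any(series$ratio == 1))
      abort_invalid("high", "no ratio == 1 level to define the high pool")
    high <- mean(series$conc_pg_ml[series$ratio == 1])
  }
  if (is.null(low)) {
    if (!any(series$ratio == 0))
      abort_invalid("low", "no ratio == 0 level to define the low pool")
    low <- mean(series$conc_pg_ml[series$ratio == 0])
  }
  series$expected <- series$ratio * high + (1 - series$ratio) * low
  if (any(series$expected == 0))
    abort_invalid("series", "expected concentration of 0 at some level")
  series$bias_pct <- 100 * (series$conc_pg_ml - series$expected) / series$expected
  per_level <- do.call(rbind, lapply(split(series, series$ratio), function(s)
    data.frame(ratio = s$ratio[1], expected = s$expected[1],
               measured = mean(s$conc_pg_ml), bias_pct = mean(s$bias_pct))))
  per_level <- per_level[order(-per_level$ratio), ]
  rownames(per_level) <- NULL

  lin <- stats::lm(conc_pg_ml ~ expected, data = series)
  poly_p <- c(quadratic = NA_real_, cubic = NA_real_)
  if (length(unique(series$expected)) >= 3) {
    quad <- stats::lm(conc_pg_ml ~ expected + I(expected^2), data = series)
    poly_p["quadratic"] <- stats::anova(lin, quad)[2, "Pr(>F)"]
    if (length(unique(series$expected)) >= 4) {
      cub <- stats::lm(conc_pg_ml ~ expected + I(expected^2) + I(expected^3),
                       data = series)
      poly_p["cubic"] <- stats::anova(quad, cub)[2, "Pr(>F)"]
    }
  }
  list(per_level = per_level,
       avg_signed_bias_pct = mean(per_level$bias_pct),
       avg_abs_bias_pct = mean(abs(per_level$bias_pct)),
       regression = list(intercept = unname(stats::coef(lin)[1]),
                         slope = unname(stats::coef(lin)[2]),
                         r_squared = summary(lin)$r.squared),
       poly_p = poly_p,
       poly_improves = any(poly_p < alpha, na.rm = TRUE))
}

#' Dilution recovery
#'
#' Recovery at each dilution is `100 * measured * factor / neat`, judged
#' against the 80-120% acceptance window (the study's criterion out to a
#' 16-fold dilution).
#'
#' @param neat_conc neat (undiluted) concentration, pg/mL, > 0
#' @param diluted data.frame with columns `factor` (>= 1) and `measured`
#' @param window acceptance window, % (default `c(80, 120)`)
#' @return data.frame with `factor`, `measured`, `recovery_pct`, `pass`
#' @export
dilution_recovery <- function(neat_conc, diluted, window = c(80, 120)) {
  assert_scalar_number(neat_conc, "neat_conc", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(diluted) ||
      !all(c("factor", "measured") %in% names(diluted)))
    abort_invalid("diluted", "needs columns factor, measured")
  if (any(diluted$factor < 1)) abort_invalid("diluted", "factors must be >= 1")
  rec <- 100 * diluted$measured * diluted$factor / neat_conc
  data.frame(factor = diluted$factor, measured = diluted$measured,
             recovery_pct = rec,
             pass = rec >= window[1] & rec <= window[2])
}

#' Interference percent differences (spiked vs control)
#'
#' Per sample, `%diff = 100 * (spiked - control) / control` (the control,
#' un-spiked measurement is the denominator). Per-interferent means are
#' reported across samples. Note the statistic is not antisymmetric under
#' swapping spiked and control: the denominator convention matters and is
#' documented here.
#'
#' @param spiked data.frame with columns `interferent`, `sample_id`,
#'   `control`, `spiked` (means in pg/mL); optional `level` label
#' @return list with `per_sample` (adds `pct_diff`) and `per_interferent`
#'   (`interferent`, `mean_pct_diff` rounded to one decimal,
#'   `mean_pct_diff_raw`)
#' @export
percent_difference <- function(spiked) {
  need <- c("interferent", "sample_id", "control", "spiked")
  if (!is.data.frame(spiked) || !all(need %in% names(spiked)))
    abort_invalid("spiked", paste("needs columns", paste(need, collapse = ", ")))
  if (any(!is.finite(spiked$control)) || any(!is.finite(spiked$spiked)))
    abort_invalid("spiked", "missing or non-finite pair")
  if (any(spiked$control <= 0))
    abort_invalid("spiked", "control means must be > 0")
  spiked$pct_diff <- 100 * (spiked$spiked - spiked$control) / spiked$control
  per_int <- do.call(rbind, lapply(split(spiked, spiked$interferent), function(s)
    data.frame(interferent = s$interferent[1],
               mean_pct_diff = round(mean(s$pct_diff), 1),
               mean_pct_diff_raw = mean(s$pct_diff),
               stringsAsFactors = FALSE)))
  rownames(per_int) <- NULL
  list(per_sample = spiked, per_interferent = per_int)
}

#' Default stability condition labels
#' @return character vector of the studied storage conditions
#' @export
stability_conditions <- function() {
  c("F/T 1", "F/T 2", "F/T 3", "2-8C 24 h", "2-8C 48 h", "RT 4 h", "RT 8 h")
}

#' Stability: average percent difference vs frozen control, with 95% CI
#'
#' Per specimen and condition, `%diff = 100 * (test - control) / control`
#' against the -70 degree C control aliquot; per condition the mean and a
#' two-sided t-based 95% CI across specimens are reported.
#'
#' @param paired data.frame with columns `condition`, `specimen`, `test`,
#'   `control` (concs in pg/mL)
#' @param conf confidence level (default 0.95)
#' @return data.frame: `condition`, `n`, `avg_pct_diff`, `lower_ci`,
#'   `upper_ci`
#' @export
stability_effect <- function(paired, conf = 0.95) {
  need <- c("condition", "specimen", "test", "control")
  if (!is.data.frame(paired) || !all(need %in% names(paired)))
    abort_invalid("paired", paste("needs columns", paste(need, collapse = ", ")))
  if (any(paired$control <= 0))
    abort_invalid("paired", "control concentrations must be > 0")
  paired$pct_diff <- 100 * (paired$test - paired$control) / paired$control
  out <- do.call(rbind, lapply(split(paired, paired$condition), function(s) {
    n <- nrow(s)
    if (n < 2)
      stop(sprintf("CI undefined for condition '%s': single specimen",
                   s$condition[1]), call. = FALSE)
    m <- mean(s$pct_diff)
    se <- stats::sd(s$pct_diff) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    data.frame(condition = s$condition[1], n = n, avg_pct_diff = m,
               lower_ci = m - tq * se, upper_ci = m + tq * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-reactivity of off-target phospho-peptides
#'
#' Apparent concentration as a percent of nominal, averaged across the
#' level series per peptide. Off-target peptides are judged against a 5%
#' criterion; the assay's target peptide is reported as percent recovery
#' instead.
#'
#' @param panel data.frame with columns `peptide`, `nominal`, `measured`
#' @param target label of the target (positive-control) peptide, default
#'   `"212/217"`
#' @param criterion off-target acceptance bound, % (default 5)
#' @return list with `per_peptide` (`peptide`, `mean_pct`, `is_target`,
#'   `flag`) and `target_recovery_pct`
#' @export
cross_reactivity <- function(panel, target = "212/217", criterion = 5) {
  need <- c("peptide", "nominal", "measured")
  if (!is.data.frame(panel) || nrow(panel) == 0 || !all(need %in% names(panel)))
    abort_invalid("panel", paste("needs rows and columns",
                                 paste(need, collapse = ", ")))
  if (any(panel$nominal <= 0)) abort_invalid("panel", "nominal must be > 0")
  per <- do.call(rbind, lapply(split(panel, panel$peptide), function(s) {
    pct <- mean(100 * s$measured / s$nominal)
    is_t <- s$peptide[1] == target
    data.frame(peptide = s$peptide[1], mean_pct = pct, is_target = is_t,
               flag = !is_t && pct >= criterion, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  tr <- per$mean_pct[per$is_target]
  list(per_peptide = per,
       target_recovery_pct = if (length(tr)) tr else NA_real_)
}
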