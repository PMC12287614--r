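# Detection capability: LoB, LoD, LLoQ (CLSI EP17-style).
#
# LoB: non-parametric 95th percentile of blank (zero-calibrator)
# measurements, rank position 0.5 + 0.95 * B with linear interpolation
# between order statistics; the assay LoB is the worst (highest) reagent
# lot. LoD = LoB + Cp * SD_L with Cp = 1.645 / (1 - 1/(4 (L - J))).
# LLoQ: the concentration at which a power-law precision profile
# (CV% = A * conc^B) crosses a CV threshold (20% by default), worst lot
# reported; the functional LLoQ additionally carries the instrument
# protocol's sample pre-dilution factor.

#' Non-parametric LoB from blank measurements
#'
#' @param blanks either a numeric vector of blank results (single lot) or a
#'   data.frame with columns `lot` and `conc_pg_ml`
#' @param prob percentile (default 0.95)
#' @return list with `lob` (assay LoB = highest lot value), `per_lot`
#'   (named vector), `pooled` (percentile of all blanks pooled)
#' @export
estimate_lob <- function(blanks, prob = 0.95) {
  if (is.numeric(blanks)) blanks <- data.frame(lot = 1L, conc_pg_ml = blanks)
  if (!is.data.frame(blanks) ||
      !all(c("lot", "conc_pg_ml") %in% names(blanks)))
    abort_invalid("blanks", "must be numeric or have columns lot, conc_pg_ml")
  x <- blanks$conc_pg_ml
  if (length(x) == 0) abort_invalid("blanks", "panel is empty")
  if (any(!is.finite(x)) || any(x < 0))
    abort_invalid("blanks", "values must be finite and >= 0")
  per_lot <- tapply(x, blanks$lot, np_percentile, prob = prob)
  counts <- table(blanks$lot)
  if (any(counts < 20))
    warning(sprintf("lot(s) %s have fewer than 20 blank replicates",
                    paste(names(counts)[counts < 20], collapse = ", ")),
            call. = FALSE)
  list(lob = max(per_lot), per_lot = per_lot,
       pooled = np_percentile(x, prob))
}

#' EP17 rank-based percentile: position 0.5 + prob * B, linear interpolation
#' between order statistics, clamped to the observed range.
#' @noRd
np_percentile <- function(x, prob = 0.95) {
  x <- sort(x)
  b <- length(x)
  pos <- 0.5 + prob * b
  if (pos <= 1) return(x[1])
  if (pos >= b) return(x[b])
  lo <- floor(pos)
  x[lo] + (pos - lo) * (x[lo + 1] - x[lo])
}

#' LoD multiplier Cp
#'
#' `Cp = 1.645 / (1 - 1/(4 (L - J)))` where L is the total number of
#' low-level results across reagent lots and J the number of distinct
#' low-level samples. Strictly decreasing in L - J with limit 1.645.
#'
#' @param L total result count
#' @param J sample count (L > J >= 1)
#' @return Cp
#' @examples
#' lod_multiplier(24, 6)  # ~1.668
#' @export
lod_multiplier <- function(L, J) {
  if (!is.numeric(L) || !is.numeric(J) || length(L) != 1 || length(J) != 1)
    abort_invalid("L", "L and J must be scalars")
  if (J < 1) abort_invalid("J", "must be >= 1")
  if (L <= J) abort_invalid("L", "must exceed J (L - J degrees of freedom)")
  1.645 / (1 - 1 / (4 * (L - J)))
}

#' LoD from a low-level replicate panel
#'
#' Pools the within-sample SD across low-level samples (replicate-count
#' weighted, i.e. pooled variance with n_i - 1 weights) and applies
#' `LoD = LoB + Cp * SD_L`.
#'
#' @param lob limit of blank (pg/mL)
#' @param panel data.frame with columns `sample_id` and `conc_pg_ml`;
#'   results for the same sample are pooled across reagent lots, so J is
#'   the number of distinct samples (6 samples tested in duplicate on 2
#'   lots give L = 24, J = 6)
#' @return list with `lod`, `sd_l`, `cp`, `L`, `J`
#' @export
estimate_lod <- function(lob, panel) {
  assert_scalar_number(lob, "lob", lower = 0)
  if (!is.data.frame(panel) ||
      !all(c("sample_id", "conc_pg_ml") %in% names(panel)))
    abort_invalid("panel", "needs columns sample_id, conc_pg_ml")
  key <- factor(panel$sample_id)
  counts <- tapply(panel$conc_pg_ml, key, length)
  if (any(counts < 2))
    abort_invalid("panel", "every sample needs >= 2 replicates")
  vars <- tapply(panel$conc_pg_ml, key, stats::var)
  df <- counts - 1
  sd_l <- sqrt(sum(vars * df) / sum(df))
  L <- nrow(panel)
  J <- nlevels(key)
  cp <- lod_multiplier(L, J)
  list(lod = lob + cp * sd_l, sd_l = sd_l, cp = cp, L = L, J = J)
}

#' Fit a precision profile (concentration vs replicate CV%)
#'
#' Per-sample replicate means and CVs are computed, then the power law
#' `CV% = A * conc^B` is fitted by linear regression of log(CV) on
#' log(conc). A CV estimated from n replicates is biased low --
#' severely so for duplicates, where the geometric mean of s/sigma is
#' exp(-0.635) ~ 0.53 -- so by default the exact expectation of
#' log(s/sigma) under normal noise, `(digamma((n-1)/2) + log 2 -
#' log(n-1)) / 2`, is subtracted from each log(CV) before the regression
#' (`bias_correct = FALSE` reproduces the naive fit). Pre-summarised
#' (mean, CV) points are used as given. A crossing with the CV threshold
#' exists only when B < 0 and at least one observed CV reaches the
#' threshold region; when every CV sits below the threshold the profile
#' is flagged `no crossing` (as happens on sufficiently precise reagent
#' lots).
#'
#' @param samples data.frame with columns `sample_id` and `conc_pg_ml`
#'   (replicate rows); alternatively columns `mean_conc` and `cv_pct` of
#'   pre-summarised points
#' @param cv_threshold CV% defining the quantitation limit (default 20)
#' @param bias_correct apply the small-sample log-CV bias correction when
#'   fitting from replicate rows (default `TRUE`)
#' @return object of class `precision_profile`: `points`, `amplitude`,
#'   `exponent`, `cv_threshold`, `has_crossing`
#' @export
fit_precision_profile <- function(samples, cv_threshold = 20,
                                  bias_correct = TRUE) {
  log_bias <- 0
  if (all(c("mean_conc", "cv_pct") %in% names(samples))) {
    pts <- data.frame(mean_conc = samples$mean_conc, cv_pct = samples$cv_pct)
  } else {
    if (!all(c("sample_id", "conc_pg_ml") %in% names(samples)))
      abort_invalid("samples",
                    "needs sample_id/conc_pg_ml rows or mean_conc/cv_pct points")
    counts <- tapply(samples$conc_pg_ml, samples$sample_id, length)
    if (any(counts < 2))
      abort_invalid("samples", "every sample needs >= 2 replicates")
    means <- tapply(samples$conc_pg_ml, samples$sample_id, mean)
    sds <- tapply(samples$conc_pg_ml, samples$sample_id, stats::sd)
    pts <- data.frame(mean_conc = as.numeric(means),
                      cv_pct = 100 * as.numeric(sds) / as.numeric(means))
    if (bias_correct) {
      n <- as.numeric(counts)
      log_bias <- (digamma((n - 1) / 2) + log(2) - log(n - 1)) / 2
    }
  }
  if (nrow(pts) < 6)
    abort_invalid("samples", "need >= 6 samples for a stable power fit")
  if (any(pts$mean_conc <= 0))
    abort_invalid("samples", "sample means must be > 0")
  if (any(pts$cv_pct < 0)) abort_invalid("samples", "CVs must be >= 0")

  usable <- pts$cv_pct > 0
  if (sum(usable) < 3)
    abort_invalid("samples", "too few non-zero CVs for a power fit")
  if (length(log_bias) == 1) log_bias <- rep(log_bias, nrow(pts))
  dat <- data.frame(lcv = log(pts$cv_pct[usable]) - log_bias[usable],
                    lconc = log(pts$mean_conc[usable]))
  fit <- stats::lm(lcv ~ lconc, data = dat)
  amplitude <- exp(unname(stats::coef(fit)[1]))
  exponent <- unname(stats::coef(fit)[2])
  has_crossing <- exponent < 0 && any(pts$cv_pct >= cv_threshold)
  structure(list(points = pts, amplitude = amplitude, exponent = exponent,
                 cv_threshold = cv_threshold, has_crossing = has_crossing),
            class = "precision_profile")
}

#' LLoQ from a precision profile
#'
#' Closed-form crossing of the fitted power law with the CV threshold:
#' `conc = (threshold / A)^(1/B)`. Lots without a crossing return
#' `NA` with reason `"no crossing"`; the assay LLoQ across lots is the
#' worst (largest) per-lot value. A crossing outside the observed
#' concentration range (e.g. when the threshold is set above every
#' observed CV) is still returned but flagged `extrapolated`.
#'
#' @param profile a `precision_profile` (or list of them, one per lot)
#' @param threshold CV% at which to evaluate the crossing; defaults to
#'   the profile's own `cv_threshold`
#' @return for a single profile, a list with `lloq`, `extrapolated`,
#'   `reason`; for a list of profiles, additionally `per_lot` and the
#'   worst-lot assay `lloq`
#' @export
lloq_at_cv <- function(profile, threshold = NULL) {
  if (inherits(profile, "precision_profile")) {
    if (!profile$has_crossing)
      return(list(lloq = NA_real_, extrapolated = FALSE,
                  reason = "no crossing: all CVs below threshold or exponent >= 0"))
    if (is.null(threshold)) threshold <- profile$cv_threshold
    x <- (threshold / profile$amplitude)^(1 / profile$exponent)
    rng <- range(profile$points$mean_conc)
    return(list(lloq = x, extrapolated = x < rng[1] || x > rng[2],
                reason = NULL))
  }
  if (is.list(profile) && all(vapply(profile, inherits, TRUE, "precision_profile"))) {
    per <- lapply(profile, lloq_at_cv, threshold = threshold)
    vals <- vapply(per, function(p) p$lloq, 0)
    if (all(is.na(vals)))
      return(list(lloq = NA_real_, per_lot = vals,
                  reason = "LLoQ indeterminate: no lot has a crossing"))
    return(list(lloq = max(vals, na.rm = TRUE), per_lot = vals, reason = NULL))
  }
  abort_invalid("profile", "must be a precision_profile or list of them")
}

#' Functional LLoQ after sample pre-dilution
#'
#' The analytical LLoQ multiplied by the instrument protocol's pre-dilution
#' factor (1:2 pre-dilution -> factor 2). LoB and LoD are deliberately
#' reported without this correction since they sit below the reportable
#' range.
#'
#' @param analytical_lloq analytical LLoQ (pg/mL)
#' @param predilution_factor dilution factor >= 1
#' @return functional LLoQ (pg/mL)
#' @examples
#' functional_lloq(0.003, 2)  # 0.006
#' @export
functional_lloq <- function(analytical_lloq, predilution_factor) {
  assert_scalar_number(analytical_lloq, "analytical_lloq", lower = 0)
  assert_scalar_number(predilution_factor, "predilution_factor", lower = 1)
  analytical_lloq * predilution_factor
}

#' Detection-limit summary with hierarchy check
#'
#' Convenience wrapper asserting LoB <= LoD <= LLoQ (a violation warns,
#' it does not error: inconsistent panels are a data problem, not a
#' programming one).
#'
#' @param lob,lod,lloq the three limits (pg/mL); `lloq` may be `NA`
#' @return named list of the three values
#' @export
detection_limit_summary <- function(lob, lod, lloq = NA_real_) {
  if (!is.na(lloq) && (lob > lod || lod > lloq))
    warning("detection limits violate LoB <= LoD <= LLoQ", call. = FALSE)
  else if (is.na(lloq) && lob > lod)
    warning("detection limits violate LoB <= LoD", call. = FALSE)
  list(lob = lob, lod = lod, lloq = lloq)
}
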