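# Four-parameter logistic (4PL) calibration.
#
# Signal model: y = d + (a - d) / (1 + (x / c)^b), the x = 0 limit being
# y = a. Unknown concentrations are interpolated through the closed-form
# inverse. Default weighting is 1/y^2 (relative least squares): digital
# immunoassay signals exhibit near-constant CV across their multi-decade
# range, and unweighted least squares lets the high-signal calibrators
# swamp the low end, leaving the zero-dose asymptote unidentifiable.
# Unweighted fitting remains available via `weighting = "none"`.

#' 4PL parameter set
#'
#' @param a signal at zero dose
#' @param d signal at infinite dose
#' @param c inflection concentration in pg/mL (> 0)
#' @param b slope factor (dimensionless, non-zero)
#' @return object of class `fourpl_params`
#' @export
fourpl_params <- function(a, d, c, b) {
  assert_scalar_number(a, "a")
  assert_scalar_number(d, "d")
  assert_scalar_number(c, "c", lower = 0, strict_lower = TRUE)
  assert_scalar_number(b, "b")
  if (a == d) abort_invalid("a", "a and d must differ (degenerate curve)")
  if (b == 0) abort_invalid("b", "slope factor must be non-zero")
  structure(list(a = a, d = d, c = c, b = b), class = "fourpl_params")
}

#' Forward 4PL signal at given concentrations
#'
#' @param params a [fourpl_params()]
#' @param conc concentrations (pg/mL, >= 0); `conc = 0` returns `a`
#' @return numeric vector of signals
#' @export
fourpl_predict <- function(params, conc) {
  stopifnot(inherits(params, "fourpl_params"))
  if (any(conc < 0)) abort_invalid("conc", "must be >= 0")
  out <- params$d + (params$a - params$d) / (1 + (conc / params$c)^params$b)
  out[conc == 0] <- params$a
  out
}

#' Fit a 4PL standard curve
#'
#' Least squares on (concentration, signal) points, e.g. the seven
#' calibrator levels plus the zero calibrator, weighted 1/y^2 by default
#' (constant-CV noise; see the methods vignette for why this is the
#' package default even though the instrument's scheme is unpublished).
#' Starting values come from the data extremes (a = mean signal at the
#' lowest concentration, d = signal at the highest, c = geometric
#' mid-range, b = 1); `nls` with the port algorithm does the
#' optimisation, with a Nelder-Mead fallback. Back-fit recovery
#' (interpolated / nominal, %) is reported per non-zero level.
#'
#' @param points data.frame with columns `conc_pg_ml` and `signal_aeb`
#'   (a `conc`/`signal` pair of columns is also accepted)
#' @param weighting `"1/y2"` (default, relative least squares) or
#'   `"none"` (unweighted)
#' @return object of class `calibration_curve`: `params`
#'   ([fourpl_params()]), `fit_range` (min/max fitted concentration),
#'   `residual_stats` (per-level `% recovery`), `rss`
#' @export
fit_4pl <- function(points, weighting = c("1/y2", "none")) {
  weighting <- match.arg(weighting)
  points <- normalize_cal_points(points)
  conc <- points$conc_pg_ml
  sig <- points$signal_aeb
  if (any(!is.finite(sig))) abort_invalid("points", "signals must be finite")
  if (any(conc < 0)) abort_invalid("points", "concentrations must be >= 0")
  if (length(unique(conc)) < 5)
    stop("4PL fit failure: need >= 5 distinct concentrations", call. = FALSE)

  ord <- order(conc)
  conc <- conc[ord]; sig <- sig[ord]
  pos <- conc > 0
  mean_by_conc <- tapply(sig, conc, mean)
  a0 <- mean_by_conc[[1]]
  d0 <- mean_by_conc[[length(mean_by_conc)]]
  if (a0 == d0)
    stop("4PL fit failure: flat response, cannot bracket", call. = FALSE)
  c0 <- exp(mean(range(log(conc[pos]))))
  b0 <- 1

  w <- if (weighting == "1/y2") 1 / pmax(sig, 1e-12)^2 else rep(1, length(sig))
  sse <- function(p) {
    a <- p[1]; d <- p[2]; cc <- exp(p[3]); b <- p[4]
    mu <- d + (a - d) / (1 + (conc / cc)^b)
    mu[conc == 0] <- a
    sum(w * (sig - mu)^2)
  }
  fit <- tryCatch({
    df <- data.frame(x = conc, y = sig, w = w)
    m <- stats::nls(
      y ~ {
        mu <- d + (a - d) / (1 + (x / exp(lc))^b)
        mu[x == 0] <- a
        mu
      },
      data = df,
      weights = w,
      start = list(a = a0, d = d0, lc = log(c0), b = b0),
      algorithm = "port",
      control = stats::nls.control(maxiter = 500, warnOnly = FALSE))
    cf <- stats::coef(m)
    list(par = c(cf["a"], cf["d"], cf["lc"], cf["b"]),
         value = sum(w * stats::resid(m)^2))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    opt <- stats::optim(c(a0, d0, log(c0), b0), sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    # polish with a second pass from the first optimum
    opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    fit <- list(par = opt$par, value = opt$value)
  }
  pars <- fit$par
  params <- tryCatch(
    fourpl_params(a = unname(pars[1]), d = unname(pars[2]),
                  c = exp(unname(pars[3])), b = unname(pars[4])),
    error = function(e)
      stop("4PL fit failure: degenerate parameter estimates", call. = FALSE))

  # monotonicity sanity over the calibrated range
  grid <- exp(seq(log(min(conc[pos])), log(max(conc)), length.out = 50))
  yy <- fourpl_predict(params, grid)
  if (any(diff(yy) * sign(yy[length(yy)] - yy[1]) < 0))
    stop("4PL fit failure: fitted curve is not monotone over the range",
         call. = FALSE)

  curve <- structure(list(params = params,
                          fit_range = range(conc),
                          residual_stats = NULL,
                          rss = fit$value),
                     class = "calibration_curve")
  lvl <- sort(unique(conc[pos]))
  rec <- vapply(lvl, function(x) {
    s <- sig[conc == x]
    back <- vapply(s, function(si)
      tryCatch(interpolate_concentration(curve, si, warn_extrapolation = FALSE),
               error = function(e) NA_real_),
      0)
    100 * mean(back, na.rm = TRUE) / x
  }, 0)
  curve$residual_stats <- data.frame(conc_pg_ml = lvl, recovery_pct = rec)
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  p <- x$params
  cat(sprintf("4PL calibration curve: a=%.4g d=%.4g c=%.4g b=%.4g\n",
              p$a, p$d, p$c, p$b))
  cat(sprintf("fit range: %.4g - %.4g pg/mL, RSS %.4g\n",
              x$fit_range[1], x$fit_range[2], x$rss))
  invisible(x)
}

#' Interpolate a concentration from a signal (4PL inverse)
#'
#' Closed form `x = c * ((a - d)/(y - d) - 1)^(1/b)`. Signals must lie
#' strictly between the asymptotes `a` and `d`; a warning flags results
#' outside the fitted concentration range.
#'
#' @param curve a `calibration_curve` (or bare [fourpl_params()])
#' @param signal signal value(s)
#' @param warn_extrapolation warn when the interpolated concentration falls
#'   outside `fit_range` (default `TRUE`)
#' @return concentration(s) in pg/mL
#' @export
interpolate_concentration <- function(curve, signal,
                                      warn_extrapolation = TRUE) {
  params <- if (inherits(curve, "calibration_curve")) curve$params else curve
  stopifnot(inherits(params, "fourpl_params"))
  lo <- min(params$a, params$d); hi <- max(params$a, params$d)
  if (any(!is.finite(signal)) || any(signal <= lo) || any(signal >= hi))
    stop(sprintf(
      "signal out of range: must lie strictly within (%.6g, %.6g)", lo, hi),
      call. = FALSE)
  x <- params$c * ((params$a - params$d) / (signal - params$d) - 1)^(1 / params$b)
  if (warn_extrapolation && inherits(curve, "calibration_curve")) {
    out <- x < curve$fit_range[1] | x > curve$fit_range[2]
    if (any(out))
      warning(sprintf("%d interpolated value(s) outside the fitted range",
                      sum(out)), call. = FALSE)
  }
  x
}

#' Readback recovery and CV at a calibrator level
#'
#' Replicate signals are interpolated through the curve; recovery is the
#' mean interpolated concentration as a percentage of the nominal level,
#' and CV the percent SD/mean of the interpolated values. The study's
#' acceptance window is 80-120% recovery.
#'
#' @param curve a `calibration_curve`
#' @param level_conc nominal concentration (pg/mL, > 0)
#' @param replicate_signals two or more replicate signals
#' @param window acceptance window on recovery, % (default `c(80, 120)`)
#' @return list with `recovery_pct`, `cv_pct`, `pass`, `concs`
#' @export
readback_recovery <- function(curve, level_conc, replicate_signals,
                              window = c(80, 120)) {
  assert_scalar_number(level_conc, "level_conc", lower = 0, strict_lower = TRUE)
  if (length(replicate_signals) < 2)
    abort_invalid("replicate_signals", "need >= 2 replicates")
  concs <- interpolate_concentration(curve, replicate_signals,
                                     warn_extrapolation = FALSE)
  m <- mean(concs)
  if (m == 0)
    stop("undefined CV: interpolated replicates are all zero", call. = FALSE)
  recovery <- 100 * m / level_conc
  cv <- 100 * stats::sd(concs) / m
  list(recovery_pct = recovery, cv_pct = cv,
       pass = recovery >= window[1] && recovery <= window[2],
       concs = concs)
}

#' @noRd
normalize_cal_points <- function(points) {
  if (!is.data.frame(points)) abort_invalid("points", "must be a data.frame")
  if (!"conc_pg_ml" %in% names(points) && "conc" %in% names(points))
    points$conc_pg_ml <- points$conc
  if (!"signal_aeb" %in% names(points) && "signal" %in% names(points))
    points$signal_aeb <- points$signal
  if (!all(c("conc_pg_ml", "signal_aeb") %in% names(points)))
    abort_invalid("points", "needs columns conc_pg_ml and signal_aeb")
  points
}
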