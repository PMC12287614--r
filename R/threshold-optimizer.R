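# Two-cutoff threshold development.
#
# The clinical cutoffs are chosen on the rate scale: a false-negative rate
# fn (the mass of the amyloid-positive distribution below the lower
# cutoff) and a false-positive rate fp (the mass of the amyloid-negative
# distribution above the upper cutoff). Group concentrations are modelled
# as log-normal; rate pairs convert to concentration cutoffs through the
# log-normal quantile function. A maximin Latin hypercube design over the
# bootstrap interquartile ranges of the four distribution parameters
# provides robustness averaging, and a Derringer-Suich desirability
# function scores predicted sensitivity, specificity and intermediate
# fraction.

#' Log-normal parameter pair (meanlog, sdlog)
#'
#' The "scale and shape" of the group distributions, in the conventional
#' (mu = meanlog, sigma = sdlog) parameterisation.
#'
#' @param mu meanlog of concentration in pg/mL
#' @param sigma sdlog (>= 0; 0 is flagged degenerate downstream)
#' @return object of class `lognormal_params`
#' @export
lognormal_params <- function(mu, sigma) {
  assert_scalar_number(mu, "mu")
  assert_scalar_number(sigma, "sigma", lower = 0)
  structure(list(mu = mu, sigma = sigma), class = "lognormal_params")
}

#' Group distribution model for a labelled cohort
#'
#' @param neg,pos [lognormal_params()] for the amyloid-negative and
#'   amyloid-positive concentration distributions
#' @param prevalence amyloid-positive fraction, in (0, 1)
#' @return object of class `group_distributions`
#' @export
group_distributions <- function(neg, pos, prevalence) {
  stopifnot(inherits(neg, "lognormal_params"), inherits(pos, "lognormal_params"))
  assert_scalar_number(prevalence, "prevalence", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  structure(list(neg = neg, pos = pos, prevalence = prevalence),
            class = "group_distributions")
}

#' Maximum-likelihood log-normal fit
#'
#' mu is the mean of the logs and sigma the population SD of the logs
#' (n denominator, the MLE). A zero sigma (all values identical) is
#' flagged degenerate with a warning.
#'
#' @param values positive concentrations, n >= 3
#' @return [lognormal_params()] with an extra `degenerate` attribute
#' @export
fit_lognormal <- function(values) {
  if (length(values) < 3) abort_invalid("values", "need n >= 3")
  if (any(!is.finite(values)) || any(values <= 0))
    abort_invalid("values", "all values must be finite and > 0")
  lv <- log(values)
  mu <- mean(lv)
  sigma <- sqrt(mean((lv - mu)^2))
  p <- lognormal_params(mu, sigma)
  if (sigma == 0) {
    warning("degenerate log-normal fit: sigma = 0", call. = FALSE)
    attr(p, "degenerate") <- TRUE
  } else attr(p, "degenerate") <- FALSE
  p
}

#' Bootstrap interquartile factor ranges for the four group parameters
#'
#' Each amyloid group is resampled with replacement `n_boot` times; a
#' log-normal is fitted to every resample, and the 25th/75th percentiles
#' of each fitted parameter across resamples define that factor's range.
#'
#' @param cohort data.frame with columns `ptau217_pg_ml` and
#'   `amyloid_status` (0/1)
#' @param n_boot number of bootstrap resamples (default 500)
#' @param seed integer seed
#' @param parametric resample from the fitted distributions instead of the
#'   data (parametric bootstrap); default `FALSE`
#' @return object of class `factor_ranges`: list of `c(low, high)` per
#'   factor `neg.mu`, `neg.sigma`, `pos.mu`, `pos.sigma`
#' @export
bootstrap_factor_ranges <- function(cohort, n_boot = 500, seed = 1L,
                                    parametric = FALSE) {
  check_cohort(cohort)
  neg <- cohort$ptau217_pg_ml[cohort$amyloid_status == 0]
  pos <- cohort$ptau217_pg_ml[cohort$amyloid_status == 1]
  for (g in list(c("negative", length(neg)), c("positive", length(pos)))) {
    n <- as.integer(g[2])
    if (n < 3) abort_invalid("cohort", sprintf("%s group has n < 3", g[1]))
    if (n < 10) warning(sprintf("%s group has n < 10; ranges will be unstable",
                                g[1]), call. = FALSE)
  }
  boot_one <- function(x, sub) {
    x <- sort(x)  # row-order invariance: resampling indexes the sorted values
    fit <- suppressWarnings(fit_lognormal(x))
    with_seed(substream_seed(seed, sub), {
      reps <- replicate(n_boot, {
        xs <- if (parametric)
          stats::rlnorm(length(x), fit$mu, fit$sigma)
        else sample(x, replace = TRUE)
        f <- suppressWarnings(fit_lognormal(xs))
        c(f$mu, f$sigma)
      })
    })
    list(mu = unname(stats::quantile(reps[1, ], c(0.25, 0.75))),
         sigma = unname(stats::quantile(reps[2, ], c(0.25, 0.75))))
  }
  bn <- boot_one(neg, "boot_neg")
  bp <- boot_one(pos, "boot_pos")
  structure(list(neg.mu = bn$mu, neg.sigma = bn$sigma,
                 pos.mu = bp$mu, pos.sigma = bp$sigma),
            class = "factor_ranges")
}

#' Maximin Latin hypercube space-filling design
#'
#' Stratifies each of the four factors into `n_runs` equal bins, each hit
#' exactly once (midpoint placement), and picks the random pairing with
#' the largest minimum pairwise Euclidean distance in the unit cube among
#' `n_candidates` candidate LHS draws.
#'
#' @param ranges a `factor_ranges` object
#' @param n_runs number of design runs (default 40)
#' @param seed integer seed
#' @param prevalence prevalence attached to each design setting (used when
#'   converting settings to [group_distributions()]); default 0.5
#' @param n_candidates candidate designs scored for the maximin criterion
#' @return list with `settings` (list of [group_distributions()]),
#'   `matrix` (n_runs x 4 design matrix on the parameter scale), and
#'   `unit` (design in the unit cube)
#' @export
space_filling_design <- function(ranges, n_runs = 40, seed = 1L,
                                 prevalence = 0.5, n_candidates = 50) {
  if (!inherits(ranges, "factor_ranges"))
    abort_invalid("ranges", "must be a factor_ranges object")
  if (n_runs < 2) abort_invalid("n_runs", "must be >= 2")
  k <- length(ranges)
  unit <- with_seed(substream_seed(seed, "lhs"), {
    best <- NULL; best_d <- -Inf
    for (i in seq_len(n_candidates)) {
      # midpoints of stratified bins, independently permuted per factor
      u <- vapply(seq_len(k), function(j)
        (sample(n_runs) - 0.5) / n_runs, numeric(n_runs))
      d <- min(stats::dist(u))
      if (d > best_d) { best <- u; best_d <- d }
    }
    # greedy exchange improvement: swapping two entries within a column
    # preserves the Latin-hypercube property
    for (it in seq_len(50 * n_runs)) {
      j <- sample.int(k, 1)
      rows <- sample.int(n_runs, 2)
      cand <- best
      cand[rows, j] <- cand[rev(rows), j]
      d <- min(stats::dist(cand))
      if (d > best_d) { best <- cand; best_d <- d }
    }
    best
  })
  lo <- vapply(ranges, `[`, 0, 1L)
  hi <- vapply(ranges, `[`, 0, 2L)
  mat <- sweep(sweep(unit, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(mat) <- names(ranges)
  settings <- lapply(seq_len(n_runs), function(i)
    group_distributions(
      neg = lognormal_params(mat[i, "neg.mu"], max(mat[i, "neg.sigma"], 1e-12)),
      pos = lognormal_params(mat[i, "pos.mu"], max(mat[i, "pos.sigma"], 1e-12)),
      prevalence = prevalence))
  list(settings = settings, matrix = mat, unit = unit)
}

#' Convert (fn, fp) rates to concentration cutoffs
#'
#' `lower = exp(pos.mu + pos.sigma * z(fn_rate))` -- the concentration
#' below which a fraction fn of the positive distribution falls -- and
#' `upper = exp(neg.mu + neg.sigma * z(1 - fp_rate))`, the concentration
#' above which a fraction fp of the negative distribution lies.
#'
#' @param dist a [group_distributions()]
#' @param fn_rate,fp_rate rates in (0, 1)
#' @return list with `lower`, `upper` (pg/mL)
#' @export
rates_to_thresholds <- function(dist, fn_rate, fp_rate) {
  stopifnot(inherits(dist, "group_distributions"))
  assert_scalar_number(fn_rate, "fn_rate", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(fp_rate, "fp_rate", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  lower <- exp(dist$pos$mu + dist$pos$sigma * stats::qnorm(fn_rate))
  upper <- exp(dist$neg$mu + dist$neg$sigma * stats::qnorm(1 - fp_rate))
  if (lower > upper)
    stop(sprintf(
      "infeasible rate pair: implied lower cutoff %.4g exceeds upper %.4g",
      lower, upper), call. = FALSE)
  list(lower = lower, upper = upper)
}

#' Closed-form two-cutoff performance under log-normal group models
#'
#' With cutoffs (L, U) implied by the rate pair: sensitivity and
#' specificity are computed among non-intermediate calls,
#' `sens = P(pos > U) / (P(pos > U) + P(pos < L))`,
#' `spec = P(neg < L) / (P(neg < L) + P(neg > U))`; the intermediate
#' fraction mixes the two groups by prevalence; accuracy is the
#' prevalence-weighted correct fraction among non-intermediate calls.
#'
#' @param dist a [group_distributions()]
#' @param fn_rate,fp_rate rates in (0, 1)
#' @return list: `sensitivity`, `specificity`, `intermediate_fraction`,
#'   `accuracy`, `lower`, `upper`
#' @export
predict_two_cutoff_performance <- function(dist, fn_rate, fp_rate) {
  thr <- rates_to_thresholds(dist, fn_rate, fp_rate)
  p_pos_below <- stats::plnorm(thr$lower, dist$pos$mu, dist$pos$sigma)
  p_pos_above <- stats::plnorm(thr$upper, dist$pos$mu, dist$pos$sigma,
                               lower.tail = FALSE)
  p_neg_below <- stats::plnorm(thr$lower, dist$neg$mu, dist$neg$sigma)
  p_neg_above <- stats::plnorm(thr$upper, dist$neg$mu, dist$neg$sigma,
                               lower.tail = FALSE)
  sens <- p_pos_above / (p_pos_above + p_pos_below)
  spec <- p_neg_below / (p_neg_below + p_neg_above)
  prev <- dist$prevalence
  intermediate <- prev * (1 - p_pos_above - p_pos_below) +
    (1 - prev) * (1 - p_neg_above - p_neg_below)
  correct <- prev * p_pos_above + (1 - prev) * p_neg_below
  called <- prev * (p_pos_above + p_pos_below) +
    (1 - prev) * (p_neg_below + p_neg_above)
  list(sensitivity = sens, specificity = spec,
       intermediate_fraction = intermediate,
       accuracy = correct / called,
       lower = thr$lower, upper = thr$upper)
}

#' Desirability specification
#'
#' One Derringer-Suich ramp per metric. For a maximised metric the
#' desirability is 0 at or below `unacceptable`, 1 at or above `target`,
#' linear in between; for a minimised metric the ramp is mirrored. The
#' overall score is the weighted geometric mean, so any metric at its
#' unacceptable bound annihilates the product.
#'
#' Defaults (documented in the methods vignette): sensitivity and
#' specificity maximised with target 0.95 / unacceptable 0.85;
#' intermediate fraction minimised with target 0.15 / unacceptable 0.45;
#' equal weights.
#'
#' @param metrics named list; each entry is a list with `target`,
#'   `unacceptable`, `direction` ("maximize"/"minimize"), `weight`
#' @return object of class `desirability_spec`
#' @export
desirability_spec <- function(metrics = list(
  sensitivity = list(target = 0.95, unacceptable = 0.85,
                     direction = "maximize", weight = 1),
  specificity = list(target = 0.95, unacceptable = 0.85,
                     direction = "maximize", weight = 1),
  intermediate_fraction = list(target = 0.15, unacceptable = 0.45,
                               direction = "minimize", weight = 1))) {
  for (nm in names(metrics)) {
    m <- metrics[[nm]]
    if (!all(c("target", "unacceptable", "direction", "weight") %in% names(m)))
      abort_invalid(nm, "needs target, unacceptable, direction, weight")
    if (m$weight <= 0) abort_invalid(nm, "weight must be > 0")
    if (!m$direction %in% c("maximize", "minimize"))
      abort_invalid(nm, "direction must be maximize or minimize")
    ok <- if (m$direction == "maximize") m$target > m$unacceptable
          else m$target < m$unacceptable
    if (!ok) abort_invalid(nm, "bounds are not ordered for the direction")
  }
  structure(metrics, class = "desirability_spec")
}

#' Overall desirability of a metric set
#'
#' @param metrics named list/vector of metric values
#' @param spec a [desirability_spec()]
#' @return scalar in `[0, 1]`
#' @export
desirability_score <- function(metrics, spec = desirability_spec()) {
  if (!inherits(spec, "desirability_spec"))
    abort_invalid("spec", "must be a desirability_spec")
  missing <- setdiff(names(spec), names(metrics))
  if (length(missing))
    abort_invalid("metrics", paste("missing metric(s):",
                                   paste(missing, collapse = ", ")))
  d <- w <- numeric(length(spec))
  for (i in seq_along(spec)) {
    m <- spec[[i]]
    x <- as.numeric(metrics[[names(spec)[i]]])
    di <- if (m$direction == "maximize")
      (x - m$unacceptable) / (m$target - m$unacceptable)
    else (m$unacceptable - x) / (m$unacceptable - m$target)
    d[i] <- min(1, max(0, di))
    w[i] <- m$weight
  }
  if (any(d == 0)) return(0)
  exp(sum(w * log(d)) / sum(w))
}

#' Optimize the two-cutoff rate pair on a labelled cohort
#'
#' Fits log-normal distributions to both amyloid groups, derives bootstrap
#' factor ranges and a maximin Latin hypercube design over them, then
#' evaluates the desirability of every rate pair on a grid at each design
#' setting (using the observed cohort prevalence). The rate pair with the
#' largest design-averaged desirability is the robust optimum; it is
#' converted to concentration cutoffs with the full-data point-estimate
#' fits. Deterministic under a fixed seed.
#'
#' @param cohort data.frame with columns `ptau217_pg_ml`,
#'   `amyloid_status`
#' @param spec a [desirability_spec()]
#' @param n_runs design runs (default 40)
#' @param n_boot bootstrap resamples for the ranges (default 500)
#' @param rate_grid candidate values for each rate (default 51 points,
#'   0.002 to 0.30)
#' @param seed integer seed
#' @return list: `thresholds` (`lower`, `upper`), `rates` (`fn_rate`,
#'   `fp_rate`), `predicted` (closed-form metrics at the point-estimate
#'   distributions), `desirability`, `design` (the design matrix),
#'   `distributions` (point-estimate [group_distributions()])
#' @export
optimize_thresholds <- function(cohort, spec = desirability_spec(),
                                n_runs = 40, n_boot = 500,
                                rate_grid = seq(0.002, 0.30, length.out = 51),
                                seed = 1L) {
  check_cohort(cohort)
  neg <- cohort$ptau217_pg_ml[cohort$amyloid_status == 0]
  pos <- cohort$ptau217_pg_ml[cohort$amyloid_status == 1]
  if (!length(neg) || !length(pos))
    abort_invalid("cohort", "both amyloid groups must be non-empty")
  prev <- length(pos) / (length(pos) + length(neg))
  point <- group_distributions(
    neg = suppressWarnings(fit_lognormal(neg)),
    pos = suppressWarnings(fit_lognormal(pos)),
    prevalence = prev)
  ranges <- bootstrap_factor_ranges(cohort, n_boot = n_boot, seed = seed)
  design <- space_filling_design(ranges, n_runs = n_runs, seed = seed,
                                 prevalence = prev)

  score <- matrix(0, length(rate_grid), length(rate_grid))
  for (setting in design$settings)
    score <- score + grid_desirability(setting, rate_grid, spec)
  score <- score / length(design$settings)
  if (all(!is.finite(score) | score <= 0))
    stop(paste("no feasible rate pair: every grid point is infeasible or has",
               "zero desirability under the given spec"), call. = FALSE)
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  fn <- rate_grid[best[1]]; fp <- rate_grid[best[2]]
  thr <- rates_to_thresholds(point, fn, fp)
  perf <- predict_two_cutoff_performance(point, fn, fp)
  list(thresholds = thr,
       rates = list(fn_rate = fn, fp_rate = fp),
       predicted = perf,
       desirability = max(score),
       design = design$matrix,
       distributions = point)
}

#' Vectorised desirability surface over a rate grid for one design setting.
#' Mirrors predict_two_cutoff_performance()/desirability_score() exactly;
#' the scalar functions remain the reference implementation the tests
#' compare against. Infeasible pairs (lower > upper) score -Inf.
#' @noRd
grid_desirability <- function(dist, rate_grid, spec) {
  k <- length(rate_grid)
  lower <- exp(dist$pos$mu + dist$pos$sigma * stats::qnorm(rate_grid))
  upper <- exp(dist$neg$mu + dist$neg$sigma * stats::qnorm(1 - rate_grid))
  # rows: fn index (lower cutoff), cols: fp index (upper cutoff)
  feasible <- outer(lower, upper, `<=`)
  p_pos_below <- stats::plnorm(lower, dist$pos$mu, dist$pos$sigma)
  p_neg_below <- stats::plnorm(lower, dist$neg$mu, dist$neg$sigma)
  p_pos_above <- stats::plnorm(upper, dist$pos$mu, dist$pos$sigma,
                               lower.tail = FALSE)
  p_neg_above <- stats::plnorm(upper, dist$neg$mu, dist$neg$sigma,
                               lower.tail = FALSE)
  PB <- matrix(p_pos_below, k, k)           # varies with fn (rows)
  NB <- matrix(p_neg_below, k, k)
  PA <- matrix(p_pos_above, k, k, byrow = TRUE)  # varies with fp (cols)
  NA_ <- matrix(p_neg_above, k, k, byrow = TRUE)
  prev <- dist$prevalence
  metrics <- list(
    sensitivity = PA / (PA + PB),
    specificity = NB / (NB + NA_),
    intermediate_fraction = prev * (1 - PA - PB) + (1 - prev) * (1 - NB - NA_),
    accuracy = (prev * PA + (1 - prev) * NB) /
      (prev * (PA + PB) + (1 - prev) * (NB + NA_)))
  logd <- matrix(0, k, k)
  wsum <- 0
  for (nm in names(spec)) {
    m <- spec[[nm]]
    x <- metrics[[nm]]
    d <- if (m$direction == "maximize")
      (x - m$unacceptable) / (m$target - m$unacceptable)
    else (m$unacceptable - x) / (m$unacceptable - m$target)
    d <- pmin(1, pmax(0, d))
    logd <- logd + m$weight * log(d)
    wsum <- wsum + m$weight
  }
  out <- exp(logd / wsum)
  out[!is.finite(out)] <- 0
  out[!feasible] <- -Inf
  out
}

#' @noRd
check_cohort <- function(cohort) {
  need <- c("ptau217_pg_ml", "amyloid_status")
  if (!is.data.frame(cohort) || !all(need %in% names(cohort)))
    abort_invalid("cohort", paste("needs columns", paste(need, collapse = ", ")))
  if (!all(cohort$amyloid_status %in% c(0, 1)))
    abort_invalid("cohort", "amyloid_status must be 0/1")
  invisible(cohort)
}
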