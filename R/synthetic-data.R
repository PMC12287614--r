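# Synthetic cohorts and bench-run tables.
#
# The generators emulate the statistical structure the downstream analyses
# assume: amyloid-stratified log-normal concentration distributions, nested
# replicate variance (instrument / day / run / residual), and 4PL
# calibration signals with multiplicative noise. They exist so the entire
# pipeline is testable with no external data.

#' Specification of a synthetic clinical cohort
#'
#' @param n_total number of participants (>= 1)
#' @param prevalence fraction of amyloid-positive participants in `[0, 1]`
#' @param neg_params,pos_params log-normal parameters (see
#'   [lognormal_params()]) for the amyloid-negative and amyloid-positive
#'   concentration distributions, in pg/mL
#' @param strata_weights named numeric vector of stratum label -> fraction;
#'   must sum to 1
#' @param seed integer seed making the cohort reproducible
#' @param exact_prevalence if `TRUE`, draw exactly
#'   `round(prevalence * n_total)` positives (quota mode) instead of
#'   Bernoulli labels; useful for fixtures
#' @return an object of class `cohort_spec`
#' @seealso [generate_cohort()], [study_cohort_spec()]
#' @export
cohort_spec <- function(n_total, prevalence, neg_params, pos_params,
                        strata_weights = c(all = 1), seed = 1L,
                        exact_prevalence = FALSE) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 1 ||
      n_total != round(n_total))
    abort_invalid("n_total", "must be a positive integer")
  assert_scalar_number(prevalence, "prevalence", lower = 0, upper = 1)
  stopifnot(inherits(neg_params, "lognormal_params"),
            inherits(pos_params, "lognormal_params"))
  if (is.null(names(strata_weights)) || any(!nzchar(names(strata_weights))))
    abort_invalid("strata_weights", "must be a named vector")
  if (abs(sum(strata_weights) - 1) > 1e-9)
    abort_invalid("strata_weights", "must sum to 1")
  if (any(strata_weights < 0))
    abort_invalid("strata_weights", "must be non-negative")
  structure(list(n_total = as.integer(n_total), prevalence = prevalence,
                 neg_params = neg_params, pos_params = pos_params,
                 strata_weights = strata_weights, seed = as.integer(seed),
                 exact_prevalence = isTRUE(exact_prevalence)),
            class = "cohort_spec")
}

#' Cohort specification matching the validation study conditions
#'
#' Defaults encode the published study population: 873 symptomatic
#' participants, 56.7% amyloid prevalence, group medians 0.046 pg/mL
#' (negative) and 0.132 pg/mL (positive). The sdlog values 0.638 and 0.545
#' are obtained by moment matching the log-normal to the printed group
#' median and SD (0.04 and 0.09 pg/mL respectively); the derivation is in
#' the methods vignette. Strata reproduce the four cohort-by-split groups
#' and their sizes.
#'
#' @param seed integer seed
#' @param n_total cohort size (default 873)
#' @param exact_prevalence passed through to [cohort_spec()]
#' @return a `cohort_spec`
#' @export
study_cohort_spec <- function(seed = 1L, n_total = 873,
                              exact_prevalence = FALSE) {
  cohort_spec(
    n_total = n_total,
    prevalence = 0.567,
    neg_params = lognormal_params(mu = log(0.046), sigma = 0.638),
    pos_params = lognormal_params(mu = log(0.132), sigma = 0.545),
    strata_weights = c(
      "cohortA:training"   = 165 / 873,
      "cohortA:validation" = 187 / 873,
      "cohortB:training"   = 281 / 873,
      "cohortB:validation" = 240 / 873),
    seed = seed,
    exact_prevalence = exact_prevalence)
}

#' Noise specification for synthetic bench runs
#'
#' @param signal_cv multiplicative CV (as a fraction) applied to 4PL
#'   signals; a log-normal factor `exp(N(0, signal_cv))` keeps signals
#'   positive
#' @param replicate_sd_components named numeric vector with entries
#'   `day`, `run`, `residual`, `instrument` giving additive SDs in pg/mL
#'   for the nested replicate error model
#' @param seed integer seed
#' @return an object of class `assay_noise_spec`
#' @export
assay_noise_spec <- function(signal_cv = 0.02,
                             replicate_sd_components = c(
                               day = 0.002, run = 0.001,
                               residual = 0.003, instrument = 0.001),
                             seed = 1L) {
  assert_scalar_number(signal_cv, "signal_cv", lower = 0)
  needed <- c("day", "run", "residual", "instrument")
  missing <- setdiff(needed, names(replicate_sd_components))
  if (length(missing))
    abort_invalid("replicate_sd_components",
                  paste("missing component(s):", paste(missing, collapse = ", ")))
  if (any(replicate_sd_components < 0))
    abort_invalid("replicate_sd_components", "SDs must be >= 0")
  structure(list(signal_cv = signal_cv,
                 replicate_sd_components = replicate_sd_components[needed],
                 seed = as.integer(seed)),
            class = "assay_noise_spec")
}

# demographic category frequencies used to dress the synthetic cohort;
# they mirror the published demographic table and matter only for
# stratified summaries, never for the concentration model
.demo_freqs <- list(
  source = c(CSF = 0.386, PET = 0.614),
  race = c("White" = 0.866, "Black or African American" = 0.089,
           "Asian" = 0.015, "Other/Unknown" = 0.030),
  ethnicity = c("Not Hispanic or Latino" = 0.856,
                "Hispanic or Latino" = 0.131, "Not reported" = 0.013),
  sex = c(Female = 0.503, Male = 0.497),
  diagnosis = c(MCI = 0.59, AD = 0.41))

#' Generate a synthetic clinical cohort
#'
#' Draws the amyloid label first (Bernoulli with the specified prevalence,
#' or quota mode when `exact_prevalence` is set), then the concentration
#' from the label's log-normal distribution. Demographic columns are drawn
#' independently from published marginal frequencies and are cosmetic.
#'
#' @param spec a [cohort_spec()]
#' @return a `data.frame` with columns `sample_id`, `cohort`, `split`,
#'   `diagnosis`, `ptau217_pg_ml`, `amyloid_status` (0/1), `source`,
#'   `race`, `ethnicity`, `age`, `sex`
#' @examples
#' cohort <- generate_cohort(study_cohort_spec(seed = 42))
#' table(cohort$amyloid_status)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    abort_invalid("spec", "must be a cohort_spec")
  n <- spec$n_total
  with_seed(substream_seed(spec$seed, "cohort"), {
    if (spec$exact_prevalence) {
      k <- round(spec$prevalence * n)
      status <- sample(rep(c(1L, 0L), c(k, n - k)))
    } else {
      status <- stats::rbinom(n, 1L, spec$prevalence)
    }
    conc <- numeric(n)
    n_pos <- sum(status == 1L)
    conc[status == 1L] <- stats::rlnorm(n_pos, spec$pos_params$mu,
                                        spec$pos_params$sigma)
    conc[status == 0L] <- stats::rlnorm(n - n_pos, spec$neg_params$mu,
                                        spec$neg_params$sigma)
    stratum <- sample(names(spec$strata_weights), n, replace = TRUE,
                      prob = spec$strata_weights)
    parts <- strsplit(stratum, ":", fixed = TRUE)
    cohort <- vapply(parts, `[`, "", 1L)
    split <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "all", "")
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      cohort = cohort,
      split = split,
      diagnosis = sample(names(.demo_freqs$diagnosis), n, TRUE,
                         .demo_freqs$diagnosis),
      ptau217_pg_ml = conc,
      amyloid_status = status,
      source = sample(names(.demo_freqs$source), n, TRUE, .demo_freqs$source),
      race = sample(names(.demo_freqs$race), n, TRUE, .demo_freqs$race),
      ethnicity = sample(names(.demo_freqs$ethnicity), n, TRUE,
                         .demo_freqs$ethnicity),
      age = round(pmin(85, pmax(43, stats::rnorm(n, 70.1, 8.0)))),
      sex = sample(names(.demo_freqs$sex), n, TRUE, .demo_freqs$sex),
      stringsAsFactors = FALSE)
  })
}

#' Default calibrator concentration series (pg/mL)
#'
#' The seven nominal calibrator levels plus the zero calibrator.
#' @return numeric vector of length 8
#' @export
calibrator_levels <- function() {
  c(0, 0.002, 0.010, 0.039, 0.156, 0.625, 2.50, 10.0)
}

#' Generate synthetic calibration signals from a 4PL curve
#'
#' @param params a [fourpl_params()] object (truth)
#' @param concs concentrations in pg/mL (>= 0); defaults to
#'   [calibrator_levels()]
#' @param noise an [assay_noise_spec()]; `signal_cv = 0` gives exact
#'   forward 4PL values
#' @param replicates number of replicate signals per level
#' @return data.frame with columns `level`, `conc_pg_ml`, `signal_aeb`
#' @export
generate_calibration_signals <- function(params, concs = calibrator_levels(),
                                         noise = assay_noise_spec(),
                                         replicates = 1L) {
  stopifnot(inherits(params, "fourpl_params"),
            inherits(noise, "assay_noise_spec"))
  if (any(!is.finite(concs)) || any(concs < 0))
    abort_invalid("concs", "must be finite and >= 0")
  if (replicates < 1) abort_invalid("replicates", "must be >= 1")
  conc_rep <- rep(concs, each = replicates)
  mu <- fourpl_predict(params, conc_rep)
  with_seed(substream_seed(noise$seed, "calibration"), {
    factor <- if (noise$signal_cv > 0)
      exp(stats::rnorm(length(conc_rep), 0, noise$signal_cv)) else 1
    data.frame(level = rep(seq_along(concs), each = replicates),
               conc_pg_ml = conc_rep,
               signal_aeb = mu * factor)
  })
}

#' Generate a nested replicate panel
#'
#' One row per replicate with keys (sample, day, run, instrument, rep).
#' The measured value is the true concentration plus independent Gaussian
#' instrument, day-within-instrument, run-within-day effects and a
#' residual, clamped at zero (concentrations cannot be negative).
#'
#' @param true_concs named or unnamed vector of true sample concentrations
#'   (pg/mL)
#' @param design list with counts `days`, `runs_per_day`, `reps_per_run`,
#'   `instruments` (all >= 1); default is the 5-day x 2-run x 2-replicate
#'   x 2-instrument layout (40 replicates per sample)
#' @param noise an [assay_noise_spec()]
#' @return data.frame with columns `sample_id`, `true_conc`, `day`, `run`,
#'   `instrument`, `analyst`, `lot`, `rep`, `conc_pg_ml`
#' @export
generate_replicate_panel <- function(true_concs,
                                     design = list(days = 5, runs_per_day = 2,
                                                   reps_per_run = 2,
                                                   instruments = 2),
                                     noise = assay_noise_spec()) {
  if (length(true_concs) == 0)
    abort_invalid("true_concs", "must be non-empty")
  if (any(!is.finite(true_concs)) || any(true_concs < 0))
    abort_invalid("true_concs", "must be finite and >= 0")
  for (f in c("days", "runs_per_day", "reps_per_run", "instruments"))
    if (is.null(design[[f]]) || design[[f]] < 1)
      abort_invalid(paste0("design$", f), "must be >= 1")
  stopifnot(inherits(noise, "assay_noise_spec"))
  ids <- names(true_concs)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_along(true_concs))
  sdc <- noise$replicate_sd_components
  grid <- expand.grid(rep = seq_len(design$reps_per_run),
                      run = seq_len(design$runs_per_day),
                      day = seq_len(design$days),
                      instrument = seq_len(design$instruments),
                      sample = seq_along(true_concs))
  with_seed(substream_seed(noise$seed, "replicate_panel"), {
    inst_key <- interaction(grid$sample, grid$instrument, drop = TRUE)
    day_key <- interaction(grid$sample, grid$instrument, grid$day, drop = TRUE)
    run_key <- interaction(grid$sample, grid$instrument, grid$day, grid$run,
                           drop = TRUE)
    inst_eff <- stats::rnorm(nlevels(inst_key), 0, sdc["instrument"])
    day_eff <- stats::rnorm(nlevels(day_key), 0, sdc["day"])
    run_eff <- stats::rnorm(nlevels(run_key), 0, sdc["run"])
    resid <- stats::rnorm(nrow(grid), 0, sdc["residual"])
    conc <- true_concs[grid$sample] + inst_eff[as.integer(inst_key)] +
      day_eff[as.integer(day_key)] + run_eff[as.integer(run_key)] + resid
    data.frame(sample_id = ids[grid$sample],
               true_conc = unname(true_concs[grid$sample]),
               day = grid$day,
               run = grid$run,
               instrument = grid$instrument,
               analyst = grid$instrument,  # one analyst per instrument
               lot = 1L,
               rep = grid$rep,
               conc_pg_ml = pmax(0, conc),
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic table to CSV (UTF-8, '.' decimal, header row)
#' @param df data.frame produced by a generator
#' @param path output path
#' @return `path`, invisibly
#' @export
write_synthetic_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
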