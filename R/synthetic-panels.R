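# Small bench-run generators for the detection-limit and LLoQ studies.
# These emulate the study's panel layouts: 20 zero-calibrator replicates
# per reagent lot, 6 low-level samples in duplicate across 2 lots, and 18
# near-LLoQ donor samples in duplicate per lot whose replicate CV follows
# a power-law precision profile.

#' Generate a blank (zero-calibrator) panel
#'
#' Measured blank "concentrations" are drawn as |N(mean, sd)| per lot,
#' mimicking the small positive readings a digital immunoassay reports on
#' the zero calibrator.
#'
#' @param n_per_lot replicates per lot (default 20)
#' @param lots number of reagent lots (default 2)
#' @param mean,sd location/spread of blank readings in pg/mL
#' @param seed integer seed
#' @return data.frame with columns `lot`, `rep`, `conc_pg_ml`
#' @export
generate_blank_panel <- function(n_per_lot = 20, lots = 2,
                                 mean = 2e-4, sd = 1.5e-4, seed = 1L) {
  if (n_per_lot < 1 || lots < 1)
    abort_invalid("n_per_lot", "counts must be >= 1")
  with_seed(substream_seed(seed, "blanks"), {
    do.call(rbind, lapply(seq_len(lots), function(l)
      data.frame(lot = l, rep = seq_len(n_per_lot),
                 conc_pg_ml = abs(stats::rnorm(n_per_lot, mean, sd)))))
  })
}

#' Generate a low-level panel for LoD estimation
#'
#' Samples in duplicate across lots; replicate error is additive Gaussian
#' with the given SD (the quantity the LoD formula pools).
#'
#' @param true_concs true low-level concentrations (default 6 samples
#'   spanning 0.001-0.004 pg/mL)
#' @param lots reagent lots (default 2)
#' @param reps replicates per sample and lot (default 2)
#' @param replicate_sd within-sample SD in pg/mL (default 6e-4)
#' @param seed integer seed
#' @return data.frame with columns `sample_id`, `lot`, `rep`,
#'   `conc_pg_ml`
#' @export
generate_low_level_panel <- function(true_concs = seq(0.001, 0.004,
                                                      length.out = 6),
                                     lots = 2, reps = 2,
                                     replicate_sd = 6e-4, seed = 1L) {
  if (!length(true_concs)) abort_invalid("true_concs", "must be non-empty")
  with_seed(substream_seed(seed, "low_level"), {
    grid <- expand.grid(rep = seq_len(reps), lot = seq_len(lots),
                        sample = seq_along(true_concs))
    data.frame(sample_id = sprintf("L%02d", grid$sample),
               lot = grid$lot, rep = grid$rep,
               conc_pg_ml = pmax(0, true_concs[grid$sample] +
                                   stats::rnorm(nrow(grid), 0, replicate_sd)))
  })
}

#' Generate a near-LLoQ duplicate panel with a power-law precision profile
#'
#' Replicate CV at true concentration x is `cv_amplitude * x^cv_exponent`
#' percent. The defaults place the 20% CV crossing at 0.003 pg/mL
#' (amplitude `20 * sqrt(0.003)`, exponent -0.5), the analytical LLoQ the
#' study world states.
#'
#' @param true_concs true concentrations (default 18 donors spanning
#'   0.0015-0.05 pg/mL, log-spaced)
#' @param reps duplicates per sample (default 2)
#' @param cv_amplitude,cv_exponent power-law coefficients (CV in %)
#' @param seed integer seed
#' @return data.frame with columns `sample_id`, `rep`, `conc_pg_ml`
#' @export
generate_lloq_panel <- function(true_concs = exp(seq(log(0.0015), log(0.05),
                                                     length.out = 18)),
                                reps = 2,
                                cv_amplitude = 20 * sqrt(0.003),
                                cv_exponent = -0.5, seed = 1L) {
  if (!length(true_concs) || any(true_concs <= 0))
    abort_invalid("true_concs", "must be non-empty and > 0")
  with_seed(substream_seed(seed, "lloq_panel"), {
    grid <- expand.grid(rep = seq_len(reps), sample = seq_along(true_concs))
    tc <- true_concs[grid$sample]
    cv <- cv_amplitude * tc^cv_exponent / 100
    data.frame(sample_id = sprintf("Q%02d", grid$sample), rep = grid$rep,
               conc_pg_ml = pmax(1e-6, tc * (1 + stats::rnorm(nrow(grid), 0, cv))))
  })
}

#' Generate an admixture linearity series
#'
#' High and low plasma pools mixed at the standard descending ratio list;
#' measured triplicates carry multiplicative noise and an optional
#' uniform proportional bias.
#'
#' @param high,low true pool concentrations (pg/mL)
#' @param ratios mixing ratios (default [admixture_ratios()])
#' @param reps replicates per level (default 3)
#' @param cv replicate CV as a fraction (default 0.05)
#' @param bias uniform proportional bias (e.g. 0.04 for +4%)
#' @param seed integer seed
#' @return data.frame with columns `ratio`, `rep`, `conc_pg_ml`
#' @export
generate_admixture_series <- function(high = 0.40, low = 0.02,
                                      ratios = admixture_ratios(), reps = 3,
                                      cv = 0.05, bias = 0, seed = 1L) {
  with_seed(substream_seed(seed, "admixture"), {
    grid <- expand.grid(rep = seq_len(reps), ratio = ratios)
    expected <- grid$ratio * high + (1 - grid$ratio) * low
    data.frame(ratio = grid$ratio, rep = grid$rep,
               conc_pg_ml = expected * (1 + bias) *
                 (1 + stats::rnorm(nrow(grid), 0, cv)))
  })
}

#' Generate paired stability measurements
#'
#' Per condition and specimen, a frozen-control and a test measurement;
#' the test condition carries a small positive proportional shift plus
#' noise, mirroring the modest storage effects seen in validated plasma
#' biomarker assays.
#'
#' @param control_concs specimen concentrations (default 6 specimens,
#'   0.024-0.114 pg/mL)
#' @param conditions condition labels (default [stability_conditions()])
#' @param effect mean proportional shift per condition (default 0.04)
#' @param cv measurement CV as a fraction (default 0.05)
#' @param seed integer seed
#' @return data.frame with columns `condition`, `specimen`, `test`,
#'   `control`
#' @export
generate_stability_pairs <- function(control_concs = seq(0.024, 0.114,
                                                         length.out = 6),
                                     conditions = stability_conditions(),
                                     effect = 0.04, cv = 0.05, seed = 1L) {
  with_seed(substream_seed(seed, "stability"), {
    grid <- expand.grid(specimen = seq_along(control_concs),
                        condition = conditions, stringsAsFactors = FALSE)
    ctrl <- control_concs[grid$specimen]
    data.frame(condition = grid$condition,
               specimen = sprintf("SP%02d", grid$specimen),
               test = ctrl * (1 + effect) * (1 + stats::rnorm(nrow(grid), 0, cv)),
               control = ctrl,
               stringsAsFactors = FALSE)
  })
}

#' Reference interference panel
#'
#' The published interference study cells: three plasma samples (0.024,
#' 0.060 and 0.114 pg/mL) spiked with eight endogenous substances, given
#' here as spiked/control concentration pairs reconstructed from the
#' observed percent differences. Feeding this table to
#' [percent_difference()] reproduces the per-interferent mean percent
#' differences of the validation study (range -2.3% to 6.6%).
#'
#' @return data.frame with columns `interferent`, `level`, `sample_id`,
#'   `control`, `spiked`
#' @export
interference_reference <- function() {
  controls <- c(low = 0.024, moderate = 0.060, high = 0.114)
  pct <- rbind(
    "Triglycerides"          = c(5.4, 4.3, -7.4),
    "Hemoglobin"             = c(6.2, 6.9, 6.6),
    "Total protein"          = c(-11.8, 0.0, 4.8),
    "Conjugated bilirubin"   = c(0.6, 10.6, 1.9),
    "Unconjugated bilirubin" = c(0.4, 10.7, 1.7),
    "HAMA"                   = c(-2.0, 15.8, 6.1),
    "Rheumatoid factor"      = c(6.6, 9.2, -0.1),
    "Biotin"                 = c(-4.9, 9.2, -4.4))
  levels <- c("Triglycerides" = "1,000 mg/dL", "Hemoglobin" = "500 mg/dL",
              "Total protein" = "1 g/dL", "Conjugated bilirubin" = "20 mg/dL",
              "Unconjugated bilirubin" = "20 mg/dL", "HAMA" = "10 ng/mL",
              "Rheumatoid factor" = "95 U/mL", "Biotin" = "0.360 mg/dL")
  out <- do.call(rbind, lapply(rownames(pct), function(int)
    data.frame(interferent = int, level = levels[[int]],
               sample_id = names(controls), control = unname(controls),
               spiked = unname(controls * (1 + pct[int, ] / 100)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
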