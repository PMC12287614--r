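test_that("zero-noise panel gives all-zero variance components", {
  quiet <- assay_noise_spec(replicate_sd_components = c(
    day = 0, run = 0, residual = 0, instrument = 0))
  panel <- generate_replicate_panel(c(A = 0.05, B = 0.10), noise = quiet)
  vc <- variance_components(panel)
  expect_equal(vc$repeatability_sd, c(0, 0))
  expect_equal(vc$within_lab_sd, c(0, 0))
  expect_equal(vc$repeatability_cv_pct, c(0, 0))
  # output schema mirrors the mean / SD / %CV reporting convention
  expect_true(all(c("sample_id", "mean_pg_ml", "repeatability_sd",
                    "repeatability_cv_pct", "within_lab_sd",
                    "within_lab_cv_pct") %in% names(vc)))
})

test_that("injected variance components are recovered within 15% on a 200-day panel", {
  target <- c(day = 0.004, run = 0.002, residual = 0.003, instrument = 0)
  noise <- assay_noise_spec(replicate_sd_components = target, seed = 2024)
  panel <- generate_replicate_panel(
    c(S = 1.0),
    design = list(days = 200, runs_per_day = 2, reps_per_run = 2,
                  instruments = 1),
    noise = noise)
  vc <- variance_components(panel)
  expect_lt(abs(vc$repeatability_sd - target["residual"]) / target["residual"], 0.15)
  expect_lt(abs(vc$day_sd - target["day"]) / target["day"], 0.15)
  expect_lt(abs(vc$run_sd - target["run"]) / target["run"], 0.15)
  # within-lab SD always >= repeatability SD
  expect_gte(vc$within_lab_sd, vc$repeatability_sd)
})

test_that("single-run input refuses within-lab precision", {
  panel <- data.frame(sample_id = "A", day = 1, run = 1,
                      conc_pg_ml = c(0.05, 0.051, 0.049))
  expect_error(variance_components(panel), "2 runs")
})

test_that("linearity: exact affine series has zero bias and no polynomial gain", {
  series <- generate_admixture_series(cv = 0, bias = 0, seed = 1)
  res <- suppressWarnings(linearity_assess(series))  # lm: perfect fit
  expect_equal(res$avg_signed_bias_pct, 0, tolerance = 1e-10)
  expect_equal(res$per_level$bias_pct, rep(0, 10), tolerance = 1e-10)
  expect_false(res$poly_improves)
  expect_equal(res$per_level$ratio, admixture_ratios())
})

test_that("a uniform +4% multiplicative bias is reported as 4% signed bias", {
  # endpoints supplied unbiased so the affine expectation stays at truth
  series <- generate_admixture_series(cv = 0, bias = 0.04, seed = 1)
  res <- suppressWarnings(linearity_assess(series, high = 0.40, low = 0.02))
  expect_equal(res$avg_signed_bias_pct, 4, tolerance = 1e-8)
  expect_equal(res$avg_abs_bias_pct, 4, tolerance = 1e-8)
})

test_that("linearity guards against a zero expected level", {
  series <- data.frame(ratio = rep(c(1, 0.5, 0), each = 2),
                       conc_pg_ml = c(1, 1, 0.5, 0.5, 0, 0))
  expect_error(linearity_assess(series, high = 1, low = 0), "expected")
})

test_that("dilution recovery arithmetic and acceptance window", {
  expect_equal(dilution_recovery(0.4, data.frame(factor = 1, measured = 0.4))$recovery_pct,
               100)
  res <- dilution_recovery(0.40, data.frame(factor = c(4, 16),
                                            measured = c(0.095, 0.030)))
  expect_equal(res$recovery_pct, c(95, 120), tolerance = 1e-10)
  expect_true(all(res$pass))
  expect_false(dilution_recovery(0.40, data.frame(factor = 2, measured = 0.15))$pass)
  expect_error(dilution_recovery(0, data.frame(factor = 1, measured = 1)),
               "neat_conc")
})

test_that("percent differences reproduce the reference interference means", {
  pd <- percent_difference(interference_reference())
  means <- setNames(pd$per_interferent$mean_pct_diff,
                    pd$per_interferent$interferent)
  expect_equal(unname(means["Hemoglobin"]), 6.6)
  expect_equal(unname(means["Total protein"]), -2.3)
  expect_equal(range(pd$per_interferent$mean_pct_diff), c(-2.3, 6.6))
  expect_equal(max(pd$per_sample$pct_diff), 15.8, tolerance = 0.05)
  # spiked == control -> 0
  z <- percent_difference(data.frame(interferent = "x", sample_id = "s",
                                     control = 0.05, spiked = 0.05))
  expect_equal(z$per_sample$pct_diff, 0)
})

test_that("percent difference denominator convention is control, not spiked", {
  df <- data.frame(interferent = "x", sample_id = "s",
                   control = 0.05, spiked = 0.06)
  fwd <- percent_difference(df)$per_sample$pct_diff
  swapped <- data.frame(interferent = "x", sample_id = "s",
                        control = 0.05, spiked = 0.04)
  bwd <- percent_difference(swapped)$per_sample$pct_diff
  expect_equal(fwd, 20)
  expect_equal(bwd, -20)  # antisymmetric only through the control denominator
})

test_that("stability means and t-intervals match a hand-computed oracle", {
  d <- c(2, 4, 6, 2, 4, 6)
  paired <- data.frame(condition = "F/T 1",
                       specimen = sprintf("s%d", 1:6),
                       control = rep(0.05, 6),
                       test = 0.05 * (1 + d / 100))
  res <- stability_effect(paired)
  expect_equal(res$avg_pct_diff, 4, tolerance = 1e-10)
  se <- sd(d) / sqrt(6)
  tq <- qt(0.975, 5)
  expect_equal(res$lower_ci, 4 - tq * se, tolerance = 1e-10)
  expect_equal(res$upper_ci, 4 + tq * se, tolerance = 1e-10)
  # all identical differences -> zero-width interval
  same <- data.frame(condition = "RT 4 h", specimen = c("a", "b"),
                     control = c(0.05, 0.08), test = c(0.05, 0.08) * 1.03)
  r2 <- stability_effect(same)
  expect_equal(r2$avg_pct_diff, 3, tolerance = 1e-10)
  expect_equal(r2$upper_ci - r2$lower_ci, 0, tolerance = 1e-8)
  single <- data.frame(condition = "x", specimen = "a", control = 1, test = 1)
  expect_error(stability_effect(single), "single specimen")
})

test_that("cross-reactivity percentages, target recovery and the 5% flag", {
  panel <- data.frame(
    peptide = rep(c("181", "212/217"), each = 4),
    nominal = rep(c(0.03, 0.3, 3, 30), 2),
    measured = c(0, 0, 0, 0, 0.882 * c(0.03, 0.3, 3), 26.46))
  res <- cross_reactivity(panel)
  p181 <- res$per_peptide[res$per_peptide$peptide == "181", ]
  expect_equal(p181$mean_pct, 0)
  expect_false(p181$flag)
  expect_equal(res$target_recovery_pct, 88.2, tolerance = 1e-10)
  hot <- data.frame(peptide = "231", nominal = c(1, 10), measured = c(0.08, 0.8))
  expect_true(cross_reactivity(hot)$per_peptide$flag)
  expect_error(cross_reactivity(data.frame()), "panel")
})
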