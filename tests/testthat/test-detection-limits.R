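test_that("LoB: all-zero blanks give 0; worst lot is reported", {
  blanks <- data.frame(lot = rep(1:2, each = 20), conc_pg_ml = 0)
  expect_equal(estimate_lob(blanks)$lob, 0)
  # lot 2 deliberately noisier: assay LoB must be the lot-2 value
  set.seed(4)
  blanks <- data.frame(lot = rep(1:2, each = 20),
                       conc_pg_ml = c(abs(rnorm(20, 2e-4, 1e-4)),
                                      abs(rnorm(20, 6e-4, 3e-4))))
  res <- estimate_lob(blanks)
  expect_equal(res$lob, max(res$per_lot))
  expect_equal(unname(res$lob), unname(res$per_lot["2"]))
})

test_that("pooled 40-blank percentile interpolates between the 38th and 39th order stats", {
  set.seed(12)
  x <- sort(runif(40))
  blanks <- data.frame(lot = rep(1:2, each = 20), conc_pg_ml = sample(x))
  res <- suppressWarnings(estimate_lob(blanks))
  # rank position 0.5 + 0.95 * 40 = 38.5
  expect_equal(res$pooled, x[38] + 0.5 * (x[39] - x[38]))
})

test_that("non-parametric percentile equals the sort-based oracle on panels <= 100", {
  set.seed(77)
  for (n in c(20, 33, 40, 61, 100)) {
    x <- rexp(n, 1000)
    blanks <- data.frame(lot = 1, conc_pg_ml = x)
    res <- suppressWarnings(estimate_lob(blanks))
    expect_equal(res$pooled, oracle_np_percentile(x), tolerance = 1e-12)
  }
  expect_error(estimate_lob(data.frame(lot = integer(), conc_pg_ml = numeric())),
               "empty")
})

test_that("Cp multiplier follows the printed formula and its limits", {
  expect_equal(lod_multiplier(24, 6), 1.645 / (1 - 1 / (4 * 18)))
  expect_equal(lod_multiplier(24, 6), 1.668, tolerance = 1e-3)
  # strictly decreasing in L - J, bounded below by 1.645
  cps <- vapply(2:60, function(L) lod_multiplier(L, 1), 0)
  expect_true(all(diff(cps) < 0))
  expect_true(all(cps > 1.645))
  expect_equal(lod_multiplier(1e7, 1), 1.645, tolerance = 1e-6)
  expect_error(lod_multiplier(6, 6), "L")
})

test_that("LoD formula: zero SD collapses to LoB; printed design reproduces 0.0015", {
  # four results per sample (duplicates on each of 2 lots) at +/- e around
  # the true value give per-sample variance 4 e^2 / 3; choose e so the
  # pooled SD is exactly 0.0006
  e <- 0.0006 * sqrt(3) / 2
  base <- seq(0.001, 0.004, length.out = 6)
  panel <- data.frame(
    sample_id = rep(sprintf("L%d", 1:6), each = 4),
    lot = rep(rep(1:2, each = 2), 6),
    conc_pg_ml = as.vector(vapply(base, function(b)
      c(b - e, b + e, b - e, b + e), numeric(4))))
  res <- estimate_lod(0.0005, panel)
  expect_equal(res$L, 24)
  expect_equal(res$J, 6)
  expect_equal(res$sd_l, 0.0006, tolerance = 1e-12)
  expect_equal(res$lod, 0.0015, tolerance = 1e-3)
  # zero spread
  panel$conc_pg_ml <- rep(base, each = 4)
  expect_equal(estimate_lod(0.0005, panel)$lod, 0.0005)
  expect_error(estimate_lod(0.0005,
                            data.frame(sample_id = "a", conc_pg_ml = 1)),
               "replicates")
})

test_that("pooled SD equals the replicate-weighted variance oracle", {
  set.seed(9)
  panel <- data.frame(sample_id = rep(letters[1:5], times = c(2, 3, 2, 4, 2)),
                      conc_pg_ml = rnorm(13, 0.002, 5e-4))
  res <- estimate_lod(0, panel)
  vars <- tapply(panel$conc_pg_ml, panel$sample_id, var)
  ns <- tapply(panel$conc_pg_ml, panel$sample_id, length)
  expect_equal(res$sd_l, sqrt(sum(vars * (ns - 1)) / sum(ns - 1)),
               tolerance = 1e-12)
})

test_that("precision profile: algebraic crossing, no-crossing flag, order invariance", {
  x <- c(1, 2, 4, 8, 16, 32)
  pts <- data.frame(mean_conc = x, cv_pct = 60 * x^(-0.5))
  prof <- fit_precision_profile(pts)
  # 60 * x^-0.5 = 20  =>  x = 9
  expect_equal(lloq_at_cv(prof)$lloq, 9, tolerance = 1e-9)
  shuffled <- fit_precision_profile(pts[c(4, 1, 6, 2, 5, 3), ])
  expect_equal(lloq_at_cv(shuffled)$lloq, 9, tolerance = 1e-9)

  low_cv <- data.frame(mean_conc = x, cv_pct = 6 * x^(-0.3))
  prof2 <- fit_precision_profile(low_cv)
  expect_false(prof2$has_crossing)
  res <- lloq_at_cv(prof2)
  expect_true(is.na(res$lloq))
  expect_match(res$reason, "no crossing")
})

test_that("closed-form crossing matches bisection on the fitted power curve", {
  set.seed(21)
  x <- exp(seq(log(0.001), log(0.05), length.out = 12))
  cv <- (20 * sqrt(0.003)) * x^(-0.5) * exp(rnorm(12, 0, 0.05))
  prof <- fit_precision_profile(data.frame(mean_conc = x, cv_pct = cv))
  closed <- lloq_at_cv(prof)$lloq
  f <- function(z) prof$amplitude * z^prof$exponent - prof$cv_threshold
  lo <- 1e-8; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_lt(abs(closed - (lo + hi) / 2), 1e-10)
})

test_that("crossing below the data range is flagged as extrapolation", {
  x <- c(1, 2, 4, 8, 16, 32)
  prof <- fit_precision_profile(data.frame(mean_conc = x, cv_pct = 60 * x^(-0.5)))
  # threshold above every observed CV: the monotone fit still crosses, but
  # below the data range
  res <- lloq_at_cv(prof, threshold = 80)
  expect_equal(res$lloq, (80 / 60)^(-2), tolerance = 1e-9)
  expect_lt(res$lloq, 1)
  expect_true(res$extrapolated)
})

test_that("worst-lot LLoQ and the functional pre-dilution correction", {
  x <- exp(seq(log(0.001), log(0.05), length.out = 10))
  lots <- list(
    fit_precision_profile(data.frame(mean_conc = x,
                                     cv_pct = (20 * sqrt(0.002)) * x^(-0.5))),
    fit_precision_profile(data.frame(mean_conc = x,
                                     cv_pct = (20 * sqrt(0.003)) * x^(-0.5))))
  res <- lloq_at_cv(lots)
  expect_equal(res$lloq, max(res$per_lot))
  expect_equal(res$lloq, 0.003, tolerance = 1e-9)
  expect_equal(functional_lloq(0.003, 2), 0.006)
  expect_equal(functional_lloq(0.42, 1), 0.42)
  expect_equal(functional_lloq(0.005, 4), 0.020)
  expect_error(functional_lloq(0.003, 0.5), "predilution_factor")
})

test_that("hierarchy LoB <= LoD <= LLoQ is asserted with a warning", {
  expect_silent(detection_limit_summary(0.0005, 0.0015, 0.003))
  expect_warning(detection_limit_summary(0.002, 0.0015, 0.003), "violate")
})
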