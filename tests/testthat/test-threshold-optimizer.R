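test_that("log-normal MLE: closed form, known-truth recovery, degenerate flag", {
  p <- fit_lognormal(exp(c(-1, 0, 1)))
  expect_equal(p$mu, 0)
  expect_equal(p$sigma, sqrt(2 / 3))
  set.seed(10)
  x <- rlnorm(10000, -3.0, 0.6)
  f <- fit_lognormal(x)
  expect_lt(abs(f$mu - (-3.0)) / 3.0, 0.02)
  expect_lt(abs(f$sigma - 0.6) / 0.6, 0.02)
  expect_warning(f0 <- fit_lognormal(rep(2, 5)), "degenerate")
  expect_true(attr(f0, "degenerate"))
  expect_error(fit_lognormal(c(1, -1, 2)), "values")
  expect_error(fit_lognormal(c(1, 2)), "values")
})

test_that("bootstrap factor ranges: degenerate groups give zero-width ranges", {
  cohort <- data.frame(ptau217_pg_ml = rep(c(0.05, 0.15), each = 20),
                       amyloid_status = rep(c(0, 1), each = 20))
  rg <- suppressWarnings(bootstrap_factor_ranges(cohort, n_boot = 50, seed = 1))
  expect_equal(diff(rg$neg.mu), 0)
  expect_equal(rg$neg.mu[1], log(0.05))
  expect_equal(diff(rg$pos.sigma), 0)
  expect_equal(rg$pos.sigma[1], 0)
})

test_that("bootstrap IQR ranges cover the true parameters about half the time", {
  true <- list(nm = log(0.046), ns = 0.638, pm = log(0.132), ps = 0.545)
  cov <- matrix(FALSE, 25, 4)
  for (r in 1:25) {
    co <- generate_cohort(cohort_spec(
      1000, 0.5, lognormal_params(true$nm, true$ns),
      lognormal_params(true$pm, true$ps), seed = 100 + r))
    rg <- bootstrap_factor_ranges(co, n_boot = 200, seed = r)
    cov[r, ] <- c(true$nm >= rg$neg.mu[1] && true$nm <= rg$neg.mu[2],
                  true$ns >= rg$neg.sigma[1] && true$ns <= rg$neg.sigma[2],
                  true$pm >= rg$pos.mu[1] && true$pm <= rg$pos.mu[2],
                  true$ps >= rg$pos.sigma[1] && true$ps <= rg$pos.sigma[2])
  }
  expect_gte(mean(cov), 0.45)          # IQR coverage ~50% by construction
  expect_true(all(colMeans(cov) >= 0.3))
})

test_that("LHS design: four factors, exact marginal stratification, maximin beats random", {
  cohort <- generate_cohort(study_cohort_spec(seed = 3))
  rg <- bootstrap_factor_ranges(cohort, n_boot = 100, seed = 3)
  des <- space_filling_design(rg, n_runs = 40, seed = 3)
  expect_equal(dim(des$matrix), c(40, 4))
  expect_length(des$settings, 40)
  # each of the 40 equal bins of each factor contains exactly one point
  for (j in 1:4) {
    bins <- floor(des$unit[, j] * 40)
    expect_equal(sort(bins), 0:39)
  }
  # min pairwise distance >= best of 100 purely random designs
  set.seed(3)
  best_random <- max(vapply(1:100, function(i)
    min(dist(matrix(runif(40 * 4), 40, 4))), 0))
  expect_gte(min(dist(des$unit)), best_random)
  expect_error(space_filling_design(rg, n_runs = 1), "n_runs")
})

test_that("rates_to_thresholds: quantile identities and infeasibility guard", {
  dist <- group_distributions(
    neg = lognormal_params(log(0.046), 0.638),
    pos = lognormal_params(log(0.132), 0.55),
    prevalence = 0.5)
  # fn = 0.5 -> lower is the positive-group median (fp kept small enough
  # that the pair stays feasible)
  thr <- rates_to_thresholds(dist, 0.5, 0.01)
  expect_equal(thr$lower, 0.132, tolerance = 1e-12)
  # z(0.05) arithmetic
  thr <- rates_to_thresholds(dist, 0.05, 0.05)
  expect_equal(thr$lower, exp(log(0.132) + 0.55 * qnorm(0.05)),
               tolerance = 1e-12)
  expect_equal(thr$lower, 0.0534, tolerance = 1e-3)
  # round trip: P(pos < lower) recovers fn_rate
  expect_equal(plnorm(thr$lower, log(0.132), 0.55), 0.05, tolerance = 1e-12)
  # monotonicity: a larger tolerated fn rate raises the lower cutoff; a
  # larger tolerated fp rate lowers the upper cutoff (both follow directly
  # from the quantile conversion)
  lowers <- vapply(c(0.01, 0.05, 0.1, 0.2),
                   function(fn) rates_to_thresholds(dist, fn, 0.01)$lower, 0)
  expect_true(all(diff(lowers) > 0))
  uppers <- vapply(c(0.01, 0.05, 0.1, 0.2),
                   function(fp) rates_to_thresholds(dist, 0.01, fp)$upper, 0)
  expect_true(all(diff(uppers) < 0))
  expect_error(rates_to_thresholds(dist, 0.49, 0.49), "infeasible")
})

test_that("closed-form performance: symmetry, vanishing zone, Monte-Carlo oracle", {
  same <- group_distributions(neg = lognormal_params(-3, 0.5),
                              pos = lognormal_params(-3, 0.5),
                              prevalence = 0.5)
  perf <- predict_two_cutoff_performance(same, 0.2, 0.2)
  expect_equal(perf$sensitivity, perf$specificity, tolerance = 1e-12)
  # fn = fp = 0.5 on identical groups collapses the zone to a point
  perf0 <- predict_two_cutoff_performance(same, 0.5, 0.5)
  expect_equal(perf0$intermediate_fraction, 0, tolerance = 1e-12)

  dist <- group_distributions(neg = lognormal_params(log(0.046), 0.638),
                              pos = lognormal_params(log(0.132), 0.545),
                              prevalence = 0.567)
  perf <- predict_two_cutoff_performance(dist, 0.05, 0.07)
  set.seed(60)
  n <- 1e6
  status <- rbinom(n, 1, dist$prevalence)
  x <- ifelse(status == 1, rlnorm(n, dist$pos$mu, dist$pos$sigma),
              rlnorm(n, dist$neg$mu, dist$neg$sigma))
  cls <- classify_two_cutoff(x, perf$lower, perf$upper)
  keep <- cls != "intermediate"
  sens_mc <- sum(cls == "positive" & status == 1) /
    sum(keep & status == 1)
  int_mc <- mean(!keep)
  se_sens <- sqrt(sens_mc * (1 - sens_mc) / sum(keep & status == 1))
  se_int <- sqrt(int_mc * (1 - int_mc) / n)
  expect_lt(abs(perf$sensitivity - sens_mc), 3 * se_sens)
  expect_lt(abs(perf$intermediate_fraction - int_mc), 3 * se_int)
})

test_that("desirability: target, annihilator and weighted geometric mean", {
  spec <- desirability_spec()
  at_target <- list(sensitivity = 0.95, specificity = 0.96,
                    intermediate_fraction = 0.10)
  expect_equal(desirability_score(at_target, spec), 1)
  bad <- list(sensitivity = 0.85, specificity = 0.96,
              intermediate_fraction = 0.10)
  expect_equal(desirability_score(bad, spec), 0)
  # two-metric hand-computed case, unequal weights
  two <- desirability_spec(list(
    a = list(target = 1, unacceptable = 0, direction = "maximize", weight = 2),
    b = list(target = 0, unacceptable = 1, direction = "minimize", weight = 1)))
  val <- desirability_score(list(a = 0.5, b = 0.2), two)
  expect_equal(val, (0.5^2 * 0.8^1)^(1 / 3), tolerance = 1e-12)
  expect_error(desirability_score(list(a = 1), two), "missing metric")
})

test_that("optimizer equals an exhaustive scalar grid search on the same inputs", {
  cohort <- generate_cohort(study_cohort_spec(seed = 7, n_total = 400))
  grid <- seq(0.002, 0.30, length.out = 51)
  opt <- optimize_thresholds(cohort, n_runs = 8, n_boot = 50,
                             rate_grid = grid, seed = 7)
  # independent oracle: scalar closed form + scalar desirability, looped
  rg <- bootstrap_factor_ranges(cohort, n_boot = 50, seed = 7)
  prev <- mean(cohort$amyloid_status)
  des <- space_filling_design(rg, n_runs = 8, seed = 7, prevalence = prev)
  spec <- desirability_spec()
  best <- c(-Inf, NA, NA)
  for (fn in grid) for (fp in grid) {
    tot <- 0
    for (s in des$settings) {
      perf <- tryCatch(predict_two_cutoff_performance(s, fn, fp),
                       error = function(e) NULL)
      tot <- tot + if (is.null(perf)) -Inf else desirability_score(perf, spec)
    }
    if (tot / 8 > best[1]) best <- c(tot / 8, fn, fp)
  }
  expect_equal(opt$rates$fn_rate, best[2])
  expect_equal(opt$rates$fp_rate, best[3])
  expect_equal(opt$desirability, best[1], tolerance = 1e-12)
})

test_that("optimizer: separable groups, determinism, row-order invariance", {
  set.seed(2)
  sep <- data.frame(
    ptau217_pg_ml = c(rlnorm(150, log(0.02), 0.3), rlnorm(150, log(0.3), 0.3)),
    amyloid_status = rep(c(0, 1), each = 150))
  # strongly separated groups only admit feasible pairs at tiny rates, so
  # the candidate grid must reach far into the tails
  opt <- optimize_thresholds(sep, n_runs = 8, n_boot = 50,
                             rate_grid = exp(seq(log(1e-7), log(0.3),
                                                 length.out = 51)),
                             seed = 2)
  expect_gt(opt$predicted$sensitivity, 0.999)
  expect_gt(opt$predicted$specificity, 0.999)
  expect_lt(opt$predicted$intermediate_fraction, 0.01)

  cohort <- generate_cohort(study_cohort_spec(seed = 11, n_total = 300))
  o1 <- optimize_thresholds(cohort, n_runs = 8, n_boot = 50, seed = 4)
  o2 <- optimize_thresholds(cohort, n_runs = 8, n_boot = 50, seed = 4)
  expect_identical(o1$thresholds, o2$thresholds)
  set.seed(99)
  o3 <- optimize_thresholds(cohort[sample(nrow(cohort)), ],
                            n_runs = 8, n_boot = 50, seed = 4)
  expect_equal(o1$rates, o3$rates)
})

test_that("optimum on study-world training data meets the 90% accuracy objective", {
  cohort <- generate_cohort(study_cohort_spec(seed = 17))
  opt <- optimize_thresholds(cohort, seed = 17)
  expect_gte(opt$predicted$accuracy, 0.90)
  # thresholds land in the neighbourhood bracketing the published candidate
  # pairs (order-of-magnitude sanity, not equality)
  expect_gt(opt$thresholds$lower, 0.035 / 3)
  expect_lt(opt$thresholds$lower, 0.035 * 3)
  expect_gt(opt$thresholds$upper, 0.090 / 3)
  expect_lt(opt$thresholds$upper, 0.090 * 3)
})
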