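# Shared fixtures and independent oracles used across test files.

# default truth for 4PL simulations: a representative digital immunoassay
# curve (low background, ~3-log dynamic range)
truth_4pl <- function() fourpl_params(a = 0.01, d = 50, c = 5, b = 1.2)

# sort-based non-parametric percentile oracle (EP17 rank convention)
oracle_np_percentile <- function(x, prob = 0.95) {
  x <- sort(x)
  pos <- 0.5 + prob * length(x)
  lo <- floor(pos); hi <- ceiling(pos)
  if (lo < 1) return(x[1])
  if (hi > length(x)) return(x[length(x)])
  if (lo == hi) return(x[lo])
  x[lo] + (pos - lo) * (x[hi] - x[lo])
}

# brute-force AUC by exhaustive pair counting
oracle_auc <- function(values, truth) {
  pos <- values[truth == 1]; neg <- values[truth == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# bisection inverse of the forward 4PL on a bracketing interval
oracle_bisect_inverse <- function(params, signal, lo = 1e-8, hi = 1e4,
                                  tol = 1e-12) {
  f <- function(x) fourpl_predict(params, x) - signal
  increasing <- f(hi) > f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if ((f(mid) > 0) == increasing) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Wilson interval from the closed form, written independently
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}

# small labelled cohort with hand-countable confusion structure
toy_cohort <- function() {
  # 20 records around cutoffs 0.04 / 0.09
  data.frame(
    ptau217_pg_ml = c(0.02, 0.03, 0.01, 0.035, 0.10, 0.12,   # negatives
                      0.05, 0.06,                              # neg intermediate
                      0.15, 0.20, 0.11, 0.30, 0.095, 0.02,    # positives
                      0.03,                                    # pos called neg
                      0.05, 0.07, 0.08, 0.089, 0.041),        # pos intermediate
    amyloid_status = c(rep(0, 8), rep(1, 12)))
}
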