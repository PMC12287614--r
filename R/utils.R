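# Internal helpers shared across modules.

#' Stop with a validation error naming the offending field
#' @noRd
abort_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Check a scalar numeric
#' @noRd
assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    abort_invalid(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    abort_invalid(field, sprintf("must be >= %g", lower))
  if (strict_upper && x >= upper)
    abort_invalid(field, sprintf("must be < %g", upper))
  if (!strict_upper && x > upper)
    abort_invalid(field, sprintf("must be <= %g", upper))
  invisible(x)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that library functions do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a deterministic per-operation substream seed from a global seed
#'
#' A single user-visible seed drives every stochastic operation in the
#' package; each operation mixes the seed with a short label so that
#' substreams are distinct but reproducible. The result is kept inside
#' the 32-bit signed integer range R requires of `set.seed()`.
#' @noRd
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1014741823
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The interval obtained by inverting the score test, used throughout the
#' clinical-performance summaries ("score proportion CI"). An exact
#' Clopper-Pearson interval is available via `method = "exact"`.
#'
#' @param x number of successes
#' @param n number of trials (>= 1)
#' @param conf confidence level (default 0.95)
#' @param method `"wilson"` (default) or `"exact"` (Clopper-Pearson)
#' @return list with `estimate`, `lower`, `upper`
#' @examples
#' wilson_ci(50, 100)
#' @export
wilson_ci <- function(x, n, conf = 0.95, method = c("wilson", "exact")) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    abort_invalid("n", "must be >= 1")
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > n)
    abort_invalid("x", "must satisfy 0 <= x <= n")
  p <- x / n
  if (method == "exact") {
    lower <- if (x == 0) 0 else stats::qbeta((1 - conf) / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - (1 - conf) / 2, x + 1, n - x)
    return(list(estimate = p, lower = lower, upper = upper))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Round-trip safe CSV reader with schema check
#' @noRd
read_table_csv <- function(path, required_cols) {
  if (!file.exists(path))
    abort_invalid("path", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    abort_invalid("path", sprintf("%s lacks required column(s): %s",
                                  path, paste(missing, collapse = ", ")))
  df
}
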