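# Effect-size and power machinery: Cohen's f^2, power under the noncentral F
# distribution with noncentrality lambda = n * f^2, and solvers for the
# minimum detectable effect size and minimum sample size.

#' Cohen's f-squared effect size
#'
#' `f2 = R2 / (1 - R2)`, the regression effect size corresponding to a
#' coefficient of determination `R2`.
#'
#' @param R2 Coefficient of determination, `0 <= R2 < 1`.
#' @return Cohen's f-squared.
#' @export
cohens_f2 <- function(R2) {
  if (any(R2 < 0 | R2 >= 1))
    stop("R2 must lie in [0, 1)", call. = FALSE)
  R2 / (1 - R2)
}

#' Power of an F test under the noncentral F distribution
#'
#' The achieved power of a level-`alpha` F test with `(d1, d2)` degrees of
#' freedom against an effect of size `f2` at sample size `n`: the
#' probability mass of the noncentral F distribution with noncentrality
#' `lambda = n * f2` beyond the central-F critical value.
#'
#' @param f2 Cohen's f-squared (>= 0).
#' @param n Sample size entering the noncentrality parameter.
#' @param d1,d2 Degrees of freedom of the test.
#' @param alpha Significance level (default 0.05).
#' @return Power in `[alpha, 1)`; exactly `alpha` when `f2 = 0`.
#' @examples
#' ncf_power(0.3557, 33, 2, 30)   # 0.8386
#' @export
ncf_power <- function(f2, n, d1, d2, alpha = 0.05) {
  stopifnot(all(f2 >= 0), n > 0, d1 > 0, d2 > 0, alpha > 0, alpha < 1)
  crit <- stats::qf(1 - alpha, d1, d2)
  stats::pf(crit, d1, d2, ncp = n * f2, lower.tail = FALSE)
}

#' Minimum detectable effect size
#'
#' Smallest Cohen's f-squared for which the level-`alpha` F test with
#' `(d1, d2)` degrees of freedom at sample size `n` reaches
#' `target_power`, found by bisection to an absolute tolerance of 1e-6.
#'
#' @param n Sample size.
#' @param d1,d2 Degrees of freedom.
#' @param alpha Significance level (default 0.05).
#' @param target_power Required power, in `(alpha, 1)` (default 0.8).
#' @return `f2_min` such that `ncf_power(f2_min, ...) >= target_power`.
#' @export
min_effect_size <- function(n, d1, d2, alpha = 0.05, target_power = 0.8) {
  if (target_power <= alpha || target_power >= 1)
    stop("target_power must lie in (alpha, 1)", call. = FALSE)
  hi <- 1
  while (ncf_power(hi, n, d1, d2, alpha) < target_power) {
    hi <- hi * 2
    if (hi > 1e6)
      stop("target power unattainable at this sample size", call. = FALSE)
  }
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (ncf_power(mid, n, d1, d2, alpha) >= target_power) hi <- mid
    else lo <- mid
  }
  hi
}

#' Minimum sample size for a given effect
#'
#' Smallest integer sample size `n` at which the level-`alpha` F test of
#' `q` predictors (with `p` responses, so `d1 = p * q` and
#' `d2 = n - q - 1`) reaches `target_power` against an effect of size
#' `f2`, with noncentrality `lambda = n * f2`.  Found by monotone search
#' and post-verified.
#'
#' @param f2 Cohen's f-squared (> 0).
#' @param q Number of predictors (default 2).
#' @param p Number of responses (default 1).
#' @param alpha Significance level (default 0.05).
#' @param target_power Required power (default 0.8).
#' @return Integer `n_min` with `power(n_min) >= target_power` and
#'   `power(n_min - 1) < target_power` (or `n_min` at the d.f. boundary).
#' @export
min_sample_size <- function(f2, q = 2, p = 1, alpha = 0.05,
                            target_power = 0.8) {
  if (f2 <= 0)
    stop("f2 must be > 0 (power never exceeds alpha at f2 = 0)",
         call. = FALSE)
  if (target_power <= alpha || target_power >= 1)
    stop("target_power must lie in (alpha, 1)", call. = FALSE)
  n <- q + 2   # smallest n with d2 = n - q - 1 >= 1
  pow <- function(n) ncf_power(f2, n, p * q, n - q - 1, alpha)
  while (pow(n) < target_power) {
    n <- n + 1
    if (n > 1e6) stop("sample size search did not converge", call. = FALSE)
  }
  stopifnot(pow(n) >= target_power,
            n == q + 2 || pow(n - 1) < target_power)
  n
}

#' Assemble a power-analysis record
#'
#' Convenience constructor for a one-row power table (the `power` result
#' schema): given an effect size (or an `R2` to convert) and the test's
#' dimensions, computes the noncentrality parameter and achieved power.
#'
#' @param f2 Cohen's f-squared; exactly one of `f2`/`R2` must be given.
#' @param R2 Coefficient of determination to convert via [cohens_f2()].
#' @param n Sample size.
#' @param d1,d2 Degrees of freedom.
#' @param alpha Significance level (default 0.05).
#' @return One-row data frame with columns `f2`, `n`, `d1`, `d2`, `alpha`,
#'   `lambda`, `power`.
#' @export
power_record <- function(f2 = NULL, R2 = NULL, n, d1, d2, alpha = 0.05) {
  if (is.null(f2) == is.null(R2))
    stop("supply exactly one of f2 or R2", call. = FALSE)
  if (is.null(f2)) f2 <- cohens_f2(R2)
  data.frame(f2 = f2, n = n, d1 = d1, d2 = d2, alpha = alpha,
             lambda = n * f2, power = ncf_power(f2, n, d1, d2, alpha))
}
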