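#' Chi-square p-value
#'
#' Survival function of the central chi-square distribution, used both for
#' the `G^2` goodness-of-fit statistic and for nested `Delta G^2` tests.
#' For `df = 2` this equals `exp(-x / 2)`.
#'
#' @param statistic Test statistic, `>= 0` (vectorized).
#' @param df Degrees of freedom, `>= 1`.
#' @return The upper-tail probability.
#' @examples
#' chisq_p(3.46, 2)  # 0.177
#' @export
chisq_p <- function(statistic, df) {
  if (any(statistic < 0)) {
    abort("`statistic` must be non-negative.",
          class = "coopunish_domain_error")
  }
  if (any(df < 1)) {
    abort("`df` must be at least 1.", class = "coopunish_domain_error")
  }
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Cohen's w effect size for chi-square tests
#'
#' `w = sqrt(statistic / N)` where `N` is the total number of observations
#' entering the test. For aggregate fits of the cooperation-and-punishment
#' model, `N` is the total number of decisions (participants times analyzed
#' trials), not the participant count — the convention under which the
#' conventional benchmarks (0.1 small, 0.3 medium, 0.5 large) apply.
#'
#' @param statistic `Delta G^2` (or chi-square) statistic, `>= 0`.
#' @param n_obs Total observation count, `> 0`.
#' @return Cohen's w.
#' @examples
#' cohens_w(272.57, 544 * 25)  # 0.14
#' @export
cohens_w <- function(statistic, n_obs) {
  if (any(statistic < 0)) {
    abort("`statistic` must be non-negative.",
          class = "coopunish_domain_error")
  }
  if (any(n_obs <= 0)) {
    abort("`n_obs` must be positive.", class = "coopunish_domain_error")
  }
  sqrt(statistic / n_obs)
}

#' Power of a chi-square test for a given effect size
#'
#' Achieved power of a chi-square test at effect size `w`, total sample
#' size `n_obs`, `df` degrees of freedom and significance level `alpha`.
#' Under the alternative the statistic is noncentral chi-square with
#' noncentrality `lambda = n_obs * w^2`; power is the probability that it
#' exceeds the central `1 - alpha` quantile.
#'
#' @param w Cohen's effect size, `>= 0`.
#' @param n_obs Total observation count.
#' @param df Degrees of freedom of the test (default 1, the df of a single
#'   equality restriction).
#' @param alpha Significance level (default 0.05).
#' @return Achieved power in `[alpha, 1]`; equals `alpha` at `w = 0`.
#' @examples
#' chisq_power(w = 0.03, n_obs = 544 * 25)
#' @export
chisq_power <- function(w, n_obs, df = 1, alpha = 0.05) {
  stopifnot(w >= 0, n_obs > 0, df >= 1, alpha > 0, alpha < 1)
  q <- qchisq(1 - alpha, df = df)
  pchisq(q, df = df, ncp = n_obs * w^2, lower.tail = FALSE)
}

#' Sensitivity analysis: minimal detectable effect size
#'
#' Solves `chisq_power(w) = power` for `w`: the smallest Cohen's w
#' detectable with the requested power at the given sample size, degrees of
#' freedom and alpha level. Solved by root bracketing to a power tolerance
#' of 1e-10, so `chisq_power(sensitivity_w(...))` returns the target power
#' to within 1e-8.
#'
#' @param power Target power, in `(0, 1)`.
#' @param n_obs Total observation count.
#' @param df Degrees of freedom (default 1).
#' @param alpha Significance level (default 0.05).
#' @return The minimal detectable w.
#' @examples
#' sensitivity_w(power = 0.95, n_obs = 544 * 25)  # about 0.03
#' @export
sensitivity_w <- function(power, n_obs, df = 1, alpha = 0.05) {
  stopifnot(n_obs > 0, df >= 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (power <= alpha) return(0)
  f <- function(w) chisq_power(w, n_obs, df, alpha) - power
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e6) {
      abort(sprintf(
        "Power %.3f is unreachable at n_obs = %g (df = %g, alpha = %g).",
        power, n_obs, df, alpha), class = "coopunish_no_solution")
    }
  }
  uniroot(f, c(0, upper), tol = 1e-14)$root
}
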