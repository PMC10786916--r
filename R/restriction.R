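#' Test an equality restriction with a nested Delta G-squared test
#'
#' Refits the model with two free parameters equated (either one parameter
#' across the two conditions, or a cross-parameter pair such as moral
#' punishment in one condition against antisocial punishment in the other)
#' and compares the restricted fit with the base fit:
#' `Delta G^2 = G^2_restricted - G^2_base`, asymptotically chi-square with
#' one degree of freedom. A significant worsening of fit means the equated
#' quantities differ. Cohen's w is attached as `sqrt(Delta G^2 / N)` with
#' `N` the total decision count.
#'
#' @inheritParams cp_fit
#' @inheritParams cp_restrict
#' @param base_fit Optional pre-computed base [cp_fit()]; refit if missing.
#' @param label Optional label for reporting; defaults to a description of
#'   the restriction.
#'
#' @return An object of class `cp_restriction` with the test statistics and
#'   both fits; see [tidy.cp_restriction()].
#' @examples
#' trials <- simulate_experiment(experiment_design("exp2"),
#'   default_true_parameters(), seed = 7)
#' counts <- aggregate_counts(trials)
#' cp_test_restriction(counts, parameter = "C", seed = 1)
#' @export
cp_test_restriction <- function(counts, model = NULL, parameter = NULL,
                                pair = NULL, base_fit = NULL, label = NULL,
                                n_starts = 5L, seed = NULL) {
  counts <- category_counts(counts)
  if (is.null(model)) model <- cp_model(unique(counts$condition))
  if (is.null(base_fit)) {
    base_fit <- cp_fit(counts, model, n_starts = n_starts, seed = seed,
                       se = "none")
  }
  restricted_model <- cp_restrict(model, parameter = parameter, pair = pair)
  restricted_fit <- cp_fit(counts, restricted_model, n_starts = n_starts,
                           seed = seed, se = "none")
  df <- restricted_fit$df - base_fit$df
  delta <- restricted_fit$g_squared - base_fit$g_squared
  if (delta < -1e-8) {
    warn(sprintf(
      "Restricted fit beat the base fit by %.3g; check base-fit convergence.",
      -delta))
  }
  delta <- max(0, delta)
  n_obs <- base_fit$n_obs
  if (is.null(label)) {
    label <- if (!is.null(parameter)) parameter else {
      paste(purrr::map_chr(pair, paste, collapse = ":"), collapse = " vs ")
    }
  }
  structure(
    list(
      parameter = label,
      delta_g_squared = delta, df = df,
      p_value = chisq_p(delta, df),
      w = cohens_w(delta, n_obs), n_obs = n_obs,
      base_fit = base_fit, restricted_fit = restricted_fit
    ),
    class = "cp_restriction"
  )
}

#' @export
print.cp_restriction <- function(x, ...) {
  cat(sprintf(
    "<cp_restriction> %s: Delta G^2(%d) = %.2f, p = %s, w = %.2f\n",
    x$parameter, x$df, x$delta_g_squared, format_p(x$p_value), x$w))
  invisible(x)
}

#' Tidy a restriction test
#'
#' @param x A `cp_restriction`.
#' @param ... Unused.
#' @return A one-row tibble: `parameter`, `delta.g.squared`, `df`,
#'   `p.value`, `w`, `n.obs`, `converged`.
#' @method tidy cp_restriction
#' @export
tidy.cp_restriction <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    delta.g.squared = x$delta_g_squared,
    df = x$df,
    p.value = x$p_value,
    w = x$w,
    n.obs = x$n_obs,
    converged = x$restricted_fit$converged && x$base_fit$converged
  )
}

#' @method glance cp_restriction
#' @export
glance.cp_restriction <- function(x, ...) tidy(x, ...)

# Reporting convention: G^2 to 2 decimals, w to 2 decimals, p to 3 decimals
# with "< 0.001" below printable precision.
format_p <- function(p) {
  ifelse(p < 0.0005, "< 0.001", sprintf("= %.3f", p))
}
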