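#' Run the full cooperation-and-punishment analysis
#'
#' Orchestrates the complete inferential battery on a two-condition counts
#' table: the base-model fit (unrestricted parameters per condition, 2
#' residual df), six equality-restriction tests — cooperation `C`, moral,
#' hypocritical and antisocial punishment and the bias `b` each equated
#' across conditions, plus the cross-parameter test of moral punishment in
#' the first condition against antisocial punishment in the second — and a
#' sensitivity analysis (minimal detectable Cohen's w at the total decision
#' count).
#'
#' @param counts A counts table, or a trial table (aggregated
#'   automatically when trial columns are detected).
#' @param battery Optional custom battery: a list of specs, each either
#'   `list(parameter = "C")` or `list(pair = list(c(cond, par), c(cond,
#'   par)), label = "...")`. Defaults to the six-test battery above.
#' @param alpha,power Significance level and target power for the
#'   sensitivity analysis (defaults 0.05, 0.95).
#' @param adjust Optional multiple-testing adjustment for the battery
#'   (`"none"` default, or any method of [stats::p.adjust()]); adjusted
#'   p-values are added as a separate column, raw p-values are always kept.
#' @param n_starts,seed Passed to [cp_fit()].
#'
#' @return An object of class `cp_report`: base fit, list of restriction
#'   tests, sensitivity result and provenance. `tidy()` returns the test
#'   table; `glance()` the base-fit summary.
#' @examples
#' trials <- simulate_experiment(experiment_design("exp2"),
#'   default_true_parameters("exp2"), seed = 3)
#' report <- run_full_analysis(trials, seed = 1)
#' tidy(report)
#' @export
run_full_analysis <- function(counts, battery = NULL, alpha = 0.05,
                              power = 0.95, adjust = "none",
                              n_starts = 5L, seed = NULL) {
  if ("punish_investment" %in% names(counts)) {
    counts <- aggregate_counts(counts)
  }
  counts <- category_counts(counts)
  conditions <- unique(counts$condition)
  model <- cp_model(conditions)
  base_fit <- cp_fit(counts, model, n_starts = n_starts, seed = seed)
  if (is.null(battery)) battery <- default_battery(conditions)
  tests <- purrr::map(battery, function(spec) {
    cp_test_restriction(
      counts, model,
      parameter = spec$parameter %||% NULL,
      pair = spec$pair %||% NULL,
      base_fit = base_fit, label = spec$label %||% NULL,
      n_starts = n_starts, seed = seed
    )
  })
  sens <- list(
    alpha = alpha, power = power, df = 1L, n_obs = sum(counts$count),
    w = sensitivity_w(power = power, n_obs = sum(counts$count), df = 1,
                      alpha = alpha)
  )
  structure(
    list(
      base_fit = base_fit, tests = tests, sensitivity = sens,
      adjust = adjust,
      provenance = list(
        seed = seed, n_starts = n_starts,
        package_version = as.character(packageVersion("coopunish")),
        conditions = conditions, n_obs = sum(counts$count)
      )
    ),
    class = "cp_report"
  )
}

# The standard six-comparison battery for a two-condition design.
default_battery <- function(conditions) {
  if (length(conditions) != 2L) {
    abort("The default battery requires exactly two conditions.",
          class = "coopunish_config_error")
  }
  list(
    list(parameter = "C"),
    list(parameter = "p_moral"),
    list(parameter = "p_hypocritical"),
    list(pair = list(c(conditions[1L], "p_moral"),
                     c(conditions[2L], "p_antisocial")),
         label = "p_moral (cond 1) vs p_antisocial (cond 2)"),
    list(parameter = "p_antisocial"),
    list(parameter = "b")
  )
}

#' Tidy the analysis report's test battery
#'
#' @param x A `cp_report`.
#' @param ... Unused.
#' @return A tibble with one row per restriction test.
#' @method tidy cp_report
#' @export
tidy.cp_report <- function(x, ...) {
  out <- dplyr::bind_rows(purrr::map(x$tests, tidy))
  if (!identical(x$adjust, "none")) {
    out$p.adjusted <- stats::p.adjust(out$p.value, method = x$adjust)
  }
  out
}

#' @method glance cp_report
#' @export
glance.cp_report <- function(x, ...) glance(x$base_fit, ...)

#' @export
print.cp_report <- function(x, ...) {
  cat("<cp_report>\n")
  g <- x$base_fit
  cat(sprintf("Base model: G^2(%d) = %.2f, p %s\n", g$df, g$g_squared,
              format_p(g$p_value)))
  for (t in x$tests) {
    cat(sprintf("  %-40s Delta G^2(%d) = %6.2f, p %s, w = %.2f\n",
                t$parameter, t$df, t$delta_g_squared, format_p(t$p_value),
                t$w))
  }
  cat(sprintf(
    "Sensitivity: minimal detectable w = %.2f (power %.2f, alpha %.2f, df %d, N = %d)\n",
    x$sensitivity$w, x$sensitivity$power, x$sensitivity$alpha,
    x$sensitivity$df, x$sensitivity$n_obs))
  invisible(x)
}

#' Serialize a report, fit or restriction test to JSON
#'
#' Full-precision values are always retained in the JSON; the markdown
#' rendering rounds to the reporting convention (G-squared 2 dp, p 3 dp,
#' w 2 dp).
#'
#' @param x A `cp_report`, `cp_fit` or `cp_restriction`.
#' @param path File path, or `NULL` to return the JSON string.
#' @return The path (invisibly) or a JSON string.
#' @export
write_report_json <- function(x, path = NULL) {
  payload <- report_payload(x)
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "cp_fit")) {
    list(
      type = "fit",
      estimates = tidy(x),
      summary = glance(x)
    )
  } else if (inherits(x, "cp_restriction")) {
    list(type = "restriction_test", result = tidy(x))
  } else if (inherits(x, "cp_report")) {
    list(
      type = "analysis_report",
      base_fit = report_payload(x$base_fit),
      tests = tidy(x),
      sensitivity = x$sensitivity,
      provenance = x$provenance
    )
  } else {
    abort("Unsupported object for JSON serialization.")
  }
}

#' Render a report as markdown
#'
#' @param x A `cp_report`.
#' @return A character vector of markdown lines (statistics rounded to the
#'   reporting convention).
#' @export
report_markdown <- function(x) {
  stopifnot(inherits(x, "cp_report"))
  g <- x$base_fit
  est <- tidy(g)
  tests <- tidy(x)
  lines <- c(
    "# Cooperation-and-punishment analysis",
    "",
    sprintf("Base model: G^2(%d) = %.2f, p %s (%s).", g$df, g$g_squared,
            format_p(g$p_value),
            if (g$converged) "converged" else "NOT converged"),
    "",
    "## Parameter estimates",
    "",
    "| condition | parameter | estimate | SE |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %s |", est$condition, est$parameter,
            est$estimate,
            ifelse(is.na(est$std.error), "-",
                   sprintf("%.3f", est$std.error))),
    "",
    "## Equality-restriction tests",
    "",
    "| restriction | Delta G^2 | df | p | w |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.2f | %d | %s | %.2f |", tests$parameter,
            tests$delta.g.squared, tests$df,
            sub("^= ", "", format_p(tests$p.value)), tests$w),
    "",
    sprintf(
      "Sensitivity: minimal detectable w = %.2f at power %.2f, alpha %.2f, df %d, N = %d.",
      x$sensitivity$w, x$sensitivity$power, x$sensitivity$alpha,
      x$sensitivity$df, x$sensitivity$n_obs)
  )
  lines
}
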