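# Shared fixtures: all data are built in code at test time.

# One-condition counts tibble from an 8-vector in the frozen category order
# (partner-defects tree first; within tree coop/punish, coop/none,
# defect/punish, defect/none).
counts_from_vector <- function(x, condition = "cond") {
  grid <- tidyr::expand_grid(condition = condition,
                             coopunish:::cp_category_grid())
  grid$count <- as.integer(x)
  grid
}

# Expected counts at C=0.6, p_moral=0.5, p_hypocritical=0.5,
# p_antisocial=0.25, b=0.2 with 400 observations per tree: all integers,
# so the empirical frequencies match the model exactly (a perfect fit).
perfect_params <- function() {
  cp_parameters(C = 0.6, p_moral = 0.5, p_hypocritical = 0.5,
                p_antisocial = 0.25, b = 0.2)
}

perfect_counts <- function(condition = "cond") {
  p <- coopunish:::prob_vector(coopunish:::as_param_vector(perfect_params()))
  counts_from_vector(round(400 * p), condition)
}

random_interior_params <- function() {
  cp_parameters(C = runif(1, 0.2, 0.8), p_moral = runif(1, 0.2, 0.8),
                p_hypocritical = runif(1, 0.2, 0.8),
                p_antisocial = runif(1, 0.2, 0.8), b = runif(1, 0.1, 0.5))
}

# Random one-condition counts with strictly interior empirical rates
# (retry until every cell of both trees is non-empty).
random_interior_counts <- function(n_per_tree = 400L, condition = "cond") {
  repeat {
    counts <- simulate_counts(
      random_interior_params(),
      tibble::tibble(condition = condition,
                     partner = c("defect", "cooperate"),
                     total = n_per_tree)
    )
    if (all(counts$count > 0L)) return(counts)
  }
}

two_condition_params <- function() {
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(condition = "cooperating-majority"),
                     cp_parameters(0.70, 0.50, 0.25, 0.15, 0.05)),
    dplyr::bind_cols(tibble::tibble(condition = "defecting-majority"),
                     cp_parameters(0.56, 0.40, 0.18, 0.06, 0.04))
  )
}
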