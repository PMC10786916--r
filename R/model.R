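#' Category probabilities of the cooperation-and-punishment model
#'
#' Computes the eight tree-conditional category probabilities for one
#' condition. The model has two processing trees, one conditional on the
#' partner defecting and one conditional on the partner cooperating. In both
#' trees the participant first cooperates with probability `C` or defects
#' with probability `1 - C`. An outcome-specific punishment process then
#' operates in three of the four cells (moral punishment when the
#' participant's cooperation meets defection, hypocritical punishment after
#' mutual defection, antisocial punishment when the participant's defection
#' meets cooperation); if it does not fire, punishment can still occur
#' through the unspecific bias `b`. Mutual cooperation offers no specific
#' reason to punish, so any punishment there reflects `b` alone.
#'
#' Within each tree the four probabilities sum to one.
#'
#' @param params Parameters for one condition, as produced by
#'   [cp_parameters()] (or any named vector/list with the same names).
#'
#' @return A tibble with columns `partner`, `decision`, `punished`,
#'   `probability` (8 rows, frozen enumeration order: partner-defects tree
#'   first; within tree cooperate/punish, cooperate/none, defect/punish,
#'   defect/none).
#' @examples
#' category_probabilities(cp_parameters(C = 0.6, p_moral = 0.5, b = 0.2))
#' @export
category_probabilities <- function(params) {
  theta <- as_param_vector(params)
  grid <- cp_category_grid()
  grid$probability <- prob_vector(theta)
  grid
}

# Fast path: 8 probabilities for one condition, frozen order, no tibbles.
prob_vector <- function(theta) {
  C <- theta[[1L]]; pm <- theta[[2L]]; ph <- theta[[3L]]
  pa <- theta[[4L]]; b <- theta[[5L]]
  c(
    # partner defects
    C * (pm + (1 - pm) * b),
    C * (1 - pm) * (1 - b),
    (1 - C) * (ph + (1 - ph) * b),
    (1 - C) * (1 - ph) * (1 - b),
    # partner cooperates
    C * b,
    C * (1 - b),
    (1 - C) * (pa + (1 - pa) * b),
    (1 - C) * (1 - pa) * (1 - b)
  )
}

#' Define a cooperation-and-punishment model specification
#'
#' A model specification lists the experimental conditions and a sharing map
#' assigning every (condition, parameter) pair to a free-parameter index.
#' Pairs with equal indices are estimated as a single free parameter. The
#' base model gives every pair its own index (for the standard two-condition
#' design: 10 free parameters, hence 2 residual degrees of freedom).
#'
#' @param conditions Character vector of condition labels (order is kept).
#'
#' @return An object of class `cp_model` with elements `conditions` and
#'   `sharing` (a tibble with columns `condition`, `parameter`, `index`).
#' @seealso [cp_restrict()], [degrees_of_freedom()]
#' @examples
#' cp_model(c("cooperating-majority", "defecting-majority"))
#' @export
cp_model <- function(conditions = c("cooperating-majority",
                                    "defecting-majority")) {
  conditions <- as.character(conditions)
  if (!length(conditions) || anyDuplicated(conditions)) {
    abort("`conditions` must be a non-empty set of distinct labels.")
  }
  sharing <- tidyr::expand_grid(
    condition = conditions,
    parameter = cp_param_names()
  )
  sharing$index <- seq_len(nrow(sharing))
  structure(
    list(conditions = conditions, sharing = sharing),
    class = "cp_model"
  )
}

#' @export
print.cp_model <- function(x, ...) {
  cat("<cp_model> ", length(x$conditions), " condition(s), ",
      n_free_parameters(x), " free parameter(s), df = ",
      degrees_of_freedom(x), "\n", sep = "")
  wide <- tidyr::pivot_wider(x$sharing, names_from = "parameter",
                             values_from = "index")
  print(wide, ...)
  invisible(x)
}

n_free_parameters <- function(model) {
  length(unique(model$sharing$index))
}

#' Impose an equality restriction on a model
#'
#' Merges two (or more) free parameters into one, producing the restricted
#' model used in a nested `Delta G^2` test. Two forms are supported:
#' equating one named parameter across all conditions (the common case, e.g.
#' `C` equal in both base-rate conditions), or equating an arbitrary pair of
#' (condition, parameter) cells — needed for the cross-parameter test of
#' moral punishment in one condition against antisocial punishment in the
#' other.
#'
#' @param model A `cp_model`.
#' @param parameter A parameter name to equate across all conditions.
#' @param pair Alternatively, a list of two `c(condition, parameter)`
#'   character vectors naming the cells to equate.
#'
#' @return A new `cp_model` with the merged sharing map (indices re-packed
#'   to `1..k`).
#' @examples
#' base <- cp_model()
#' cp_restrict(base, parameter = "C")
#' cp_restrict(base, pair = list(
#'   c("cooperating-majority", "p_moral"),
#'   c("defecting-majority", "p_antisocial")
#' ))
#' @export
cp_restrict <- function(model, parameter = NULL, pair = NULL) {
  stopifnot(inherits(model, "cp_model"))
  sharing <- model$sharing
  if (!is.null(parameter)) {
    if (!parameter %in% cp_param_names()) {
      abort(sprintf("Unknown parameter `%s`. Known: %s.", parameter,
                    paste(cp_param_names(), collapse = ", ")),
            class = "coopunish_config_error")
    }
    rows <- which(sharing$parameter == parameter)
  } else if (!is.null(pair)) {
    if (length(pair) != 2L) {
      abort("`pair` must list exactly two (condition, parameter) cells.",
            class = "coopunish_config_error")
    }
    rows <- purrr::map_int(pair, function(cell) {
      i <- which(sharing$condition == cell[[1L]] &
                   sharing$parameter == cell[[2L]])
      if (!length(i)) {
        abort(sprintf("No cell (condition = '%s', parameter = '%s') in model.",
                      cell[[1L]], cell[[2L]]),
              class = "coopunish_config_error")
      }
      i
    })
  } else {
    abort("Supply either `parameter` or `pair`.",
          class = "coopunish_config_error")
  }
  idx <- unique(sharing$index[rows])
  if (length(idx) < 2L) {
    abort("The named cells are already equated in this model.",
          class = "coopunish_config_error")
  }
  sharing$index[sharing$index %in% idx] <- min(idx)
  sharing$index <- match(sharing$index, sort(unique(sharing$index)))
  model$sharing <- sharing
  model
}

#' Residual degrees of freedom of a model specification
#'
#' Each processing tree contributes three free category probabilities (four
#' categories constrained to sum to one); the model spends one degree of
#' freedom per free parameter index. With two trees per condition,
#' `df = 3 * 2 * n_conditions - n_free_parameters`. The two-condition base
#' model therefore has `df = 12 - 10 = 2`.
#'
#' @param model A `cp_model`.
#' @return A non-negative integer.
#' @examples
#' degrees_of_freedom(cp_model())  # 2
#' @export
degrees_of_freedom <- function(model) {
  stopifnot(inherits(model, "cp_model"))
  df <- 3L * 2L * length(model$conditions) - n_free_parameters(model)
  if (df < 0L) {
    abort("Model has more free parameters than free category probabilities.",
          class = "coopunish_config_error")
  }
  df
}

# Sharing map as an integer matrix [condition x parameter] of free indices.
sharing_matrix <- function(model) {
  wide <- tidyr::pivot_wider(model$sharing, names_from = "parameter",
                             values_from = "index")
  m <- as.matrix(wide[cp_param_names()])
  rownames(m) <- wide$condition
  m[model$conditions, , drop = FALSE]
}

#' Export the model structure as an EQN-style text file
#'
#' Writes one line per tree branch in the classic EQN layout used by MPT
#' tooling: a first line with the number of branch lines, then
#' `tree<TAB>category<TAB>product-of-terms`. Tree labels are
#' `<condition>.partner_defects` / `<condition>.partner_cooperates`;
#' category labels combine the participant decision and punishment outcome.
#' Parameters are suffixed with the 1-based condition number when the model
#' has several conditions so that equated cells share a symbol.
#'
#' @param model A `cp_model`.
#' @param path File path to write to, or `NULL` to return the lines.
#' @return Invisibly (or visibly when `path` is `NULL`), a character vector
#'   of EQN lines.
#' @export
write_eqn <- function(model, path = NULL) {
  stopifnot(inherits(model, "cp_model"))
  m <- sharing_matrix(model)
  # one symbol per free index, named after the first (condition, parameter)
  # cell that uses it
  sym <- character(max(m))
  multi <- length(model$conditions) > 1L
  for (ci in seq_along(model$conditions)) {
    for (pi in seq_len(ncol(m))) {
      k <- m[ci, pi]
      if (sym[k] == "") {
        sym[k] <- if (multi) paste0(colnames(m)[pi], "_", ci) else colnames(m)[pi]
      }
    }
  }
  lines <- character(0)
  for (ci in seq_along(model$conditions)) {
    cond <- model$conditions[ci]
    s <- sym[m[ci, ]]
    C <- s[1L]; pm <- s[2L]; ph <- s[3L]; pa <- s[4L]; b <- s[5L]
    td <- paste0(cond, ".partner_defects")
    tc <- paste0(cond, ".partner_cooperates")
    branch <- function(tree, cat, terms) paste(tree, cat, terms, sep = "\t")
    lines <- c(
      lines,
      branch(td, "cooperate_punish", paste0(C, "*", pm)),
      branch(td, "cooperate_punish", paste0(C, "*(1-", pm, ")*", b)),
      branch(td, "cooperate_none",   paste0(C, "*(1-", pm, ")*(1-", b, ")")),
      branch(td, "defect_punish",    paste0("(1-", C, ")*", ph)),
      branch(td, "defect_punish",    paste0("(1-", C, ")*(1-", ph, ")*", b)),
      branch(td, "defect_none",      paste0("(1-", C, ")*(1-", ph, ")*(1-", b, ")")),
      branch(tc, "cooperate_punish", paste0(C, "*", b)),
      branch(tc, "cooperate_none",   paste0(C, "*(1-", b, ")")),
      branch(tc, "defect_punish",    paste0("(1-", C, ")*", pa)),
      branch(tc, "defect_punish",    paste0("(1-", C, ")*(1-", pa, ")*", b)),
      branch(tc, "defect_none",      paste0("(1-", C, ")*(1-", pa, ")*(1-", b, ")"))
    )
  }
  lines <- c(as.character(length(lines)), lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
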