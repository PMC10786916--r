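#' Construct a parameter set for the cooperation-and-punishment model
#'
#' The model describes one experimental condition with five latent
#' probabilities: `C`, the participant's propensity to cooperate (assumed
#' independent of the partner's move, which is revealed only afterwards);
#' `p_moral`, moral punishment of a defecting partner by a cooperating
#' participant; `p_hypocritical`, punishment after mutual defection;
#' `p_antisocial`, punishment of a cooperating partner by a defecting
#' participant; and `b`, an unspecific punishment bias that can produce
#' punishment in any cell, identified from the mutual-cooperation cell where
#' no outcome-specific punishment process operates.
#'
#' @param C Probability of participant cooperation, in `[0, 1]`.
#' @param p_moral Probability of moral punishment of unilateral partner
#'   defection.
#' @param p_hypocritical Probability of hypocritical punishment following
#'   mutual defection.
#' @param p_antisocial Probability of antisocial punishment of unilateral
#'   partner cooperation.
#' @param b Unspecific punishment-bias probability.
#'
#' @return A one-row tibble with columns `C`, `p_moral`, `p_hypocritical`,
#'   `p_antisocial`, `b`.
#' @examples
#' cp_parameters(C = 0.7, p_moral = 0.4, b = 0.05)
#' @export
cp_parameters <- function(C, p_moral = 0, p_hypocritical = 0,
                          p_antisocial = 0, b = 0) {
  values <- c(C = C, p_moral = p_moral, p_hypocritical = p_hypocritical,
              p_antisocial = p_antisocial, b = b)
  validate_probabilities(values)
  tibble::as_tibble(as.list(values))
}

validate_probabilities <- function(values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      abort(sprintf("Parameter `%s` must be a single numeric value.", nm),
            class = "coopunish_domain_error")
    }
    if (v < 0 || v > 1) {
      abort(sprintf("Parameter `%s` = %g lies outside [0, 1].", nm, v),
            class = "coopunish_domain_error")
    }
  }
  invisible(values)
}

# Coerce a parameter input (one-row tibble/data.frame, named vector or list)
# to a named numeric vector in canonical order.
as_param_vector <- function(params) {
  nms <- cp_param_names()
  if (is.data.frame(params)) {
    if (nrow(params) != 1L) {
      abort("Expected exactly one row of parameters for a single condition.")
    }
    params <- as.list(params[intersect(names(params), nms)])
  }
  params <- unlist(params)
  missing <- setdiff(nms, names(params))
  if (length(missing)) {
    abort(paste0("Missing parameter(s): ", paste(missing, collapse = ", ")))
  }
  out <- as.numeric(params[nms])
  names(out) <- nms
  validate_probabilities(out)
  out
}

# Multi-condition parameter table: one row per condition, columns
# condition + the five parameters.
as_param_table <- function(params, conditions) {
  if (is.data.frame(params) && "condition" %in% names(params)) {
    missing <- setdiff(conditions, params$condition)
    if (length(missing)) {
      abort(paste0("No parameters supplied for condition(s): ",
                   paste(missing, collapse = ", ")))
    }
    rows <- purrr::map(conditions, function(cond) {
      row <- params[params$condition == cond, , drop = FALSE]
      as_param_vector(row[setdiff(names(row), "condition")])
    })
  } else if (length(conditions) == 1L) {
    rows <- list(as_param_vector(params))
  } else {
    abort("For multiple conditions supply a data frame with a `condition` column.")
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(condition = conditions), out)
}
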