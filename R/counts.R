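#' Validate and order a table of category counts
#'
#' Category counts are the observed data entering the model fit: per
#' condition, the number of decisions falling into each of the eight cells
#' defined by partner tree (cooperate/defect), participant decision
#' (cooperate/defect) and punishment (yes/no). Counts are pooled over
#' participants and trials.
#'
#' @param counts A data frame with columns `condition`, `partner`,
#'   `decision`, `punished`, `count`. Missing cells are filled with zero.
#' @param conditions Optional condition order; defaults to order of first
#'   appearance.
#'
#' @return A tibble in the frozen category order (8 rows per condition),
#'   with integer-valued non-negative counts.
#' @examples
#' trials <- simulate_experiment(experiment_design("exp2"),
#'   default_true_parameters(), seed = 1)
#' category_counts(aggregate_counts(trials))
#' @export
category_counts <- function(counts, conditions = NULL) {
  need <- c("condition", "partner", "decision", "punished", "count")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    abort(paste0("Counts table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(conditions)) conditions <- unique(as.character(counts$condition))
  bad <- setdiff(unique(as.character(counts$condition)), conditions)
  if (length(bad)) {
    abort(paste0("Unknown condition label(s): ", paste(bad, collapse = ", "),
                 "; expected: ", paste(conditions, collapse = ", ")))
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    abort("Counts must be non-negative integers.")
  }
  grid <- tidyr::expand_grid(condition = conditions, cp_category_grid())
  out <- dplyr::left_join(
    grid,
    dplyr::mutate(counts, condition = as.character(.data$condition)),
    by = c("condition", "partner", "decision", "punished")
  )
  out$count <- as.integer(dplyr::coalesce(out$count, 0L))
  out
}

# Counts as an integer matrix [condition x 8] in frozen category order.
as_count_matrix <- function(counts, conditions) {
  counts <- category_counts(counts, conditions)
  m <- matrix(counts$count, nrow = length(conditions), ncol = 8L, byrow = TRUE)
  rownames(m) <- conditions
  m
}

#' Per-tree observation totals
#'
#' @param counts A counts table (see [category_counts()]).
#' @return A tibble with columns `condition`, `partner`, `total`.
#' @export
tree_totals <- function(counts) {
  counts <- category_counts(counts)
  dplyr::summarise(
    dplyr::group_by(counts, .data$condition, .data$partner),
    total = sum(.data$count), .groups = "drop"
  )
}

#' Read and write category-count tables
#'
#' Counts are stored as a tab-delimited text file with header columns
#' `condition`, `partner`, `decision`, `punished`, `count` (the frozen
#' category order is restored on read), or as JSON with the same records.
#'
#' @param counts A counts table.
#' @param path File path. Paths ending in `.json` use JSON, otherwise TSV.
#' @return `write_counts()` returns `path` invisibly; `read_counts()`
#'   returns a validated counts tibble.
#' @export
write_counts <- function(counts, path) {
  counts <- category_counts(counts)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(counts, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
  }
  category_counts(df)
}
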