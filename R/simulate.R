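#' Describe one experimental condition of the simulated design
#'
#' A condition fixes the partner base-rate manipulation (the programmed
#' proportion of partner cooperation), the sample size, the number of
#' analyzed trials per participant, whether partners punish the
#' participant's unilateral defection (they always do in the two-sided
#' punishment design, never in the unilateral design), and the starting
#' endowment.
#'
#' @param label Condition label.
#' @param partner_coop_rate Programmed proportion of partner-cooperation
#'   trials (0.6 for the cooperating majority, 0.4 for the defecting
#'   majority).
#' @param n_participants Number of participants in the condition.
#' @param trials Analyzed trials per participant (default 25).
#' @param partner_punishes_defection Whether partners always fine the
#'   participant's unilateral defection.
#' @param endowment Starting account balance in points (default 150).
#' @return A one-row design tibble.
#' @export
condition_design <- function(label, partner_coop_rate, n_participants,
                             trials = 25L,
                             partner_punishes_defection = FALSE,
                             endowment = 150) {
  stopifnot(partner_coop_rate >= 0, partner_coop_rate <= 1,
            n_participants >= 1, trials >= 1)
  tibble::tibble(
    condition = as.character(label),
    partner_coop_rate = partner_coop_rate,
    n_participants = as.integer(n_participants),
    trials = as.integer(trials),
    partner_punishes_defection = isTRUE(partner_punishes_defection),
    endowment = endowment
  )
}

#' Preset experimental designs
#'
#' `"exp1"`: 278 + 266 participants, partner cooperation rates 0.6 / 0.4,
#' 25 analyzed trials, partners always punish unilateral defection.
#' `"exp2"`: 250 + 245 participants, same base rates and trial count, no
#' partner punishment (the punishment option is unilateral).
#'
#' @param preset `"exp1"` or `"exp2"`.
#' @return A two-row design tibble (see [condition_design()]).
#' @examples
#' experiment_design("exp1")
#' @export
experiment_design <- function(preset = c("exp1", "exp2")) {
  preset <- match.arg(preset)
  if (preset == "exp1") {
    dplyr::bind_rows(
      condition_design("cooperating-majority", 0.6, 278L,
                       partner_punishes_defection = TRUE),
      condition_design("defecting-majority", 0.4, 266L,
                       partner_punishes_defection = TRUE)
    )
  } else {
    dplyr::bind_rows(
      condition_design("cooperating-majority", 0.6, 250L),
      condition_design("defecting-majority", 0.4, 245L)
    )
  }
}

#' Default generating parameters for simulations
#'
#' Cooperation probabilities follow the observed behavioral cooperation
#' rates (0.70 / 0.56 with partner punishment; closer alignment with the
#' 0.6 / 0.4 base rates without it). Punishment parameters reflect the
#' qualitative pattern of the fitted estimates: moral punishment clearly
#' the most likely, higher under a cooperating majority; hypocritical
#' punishment intermediate; antisocial punishment rare; a small unspecific
#' bias.
#'
#' @param preset `"exp1"` or `"exp2"`.
#' @return A two-row parameter table (`condition` plus the five model
#'   parameters), suitable for [simulate_experiment()].
#' @export
default_true_parameters <- function(preset = c("exp1", "exp2")) {
  preset <- match.arg(preset)
  if (preset == "exp1") {
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(condition = "cooperating-majority"),
                       cp_parameters(0.70, 0.50, 0.25, 0.15, 0.05)),
      dplyr::bind_cols(tibble::tibble(condition = "defecting-majority"),
                       cp_parameters(0.56, 0.40, 0.18, 0.06, 0.04))
    )
  } else {
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(condition = "cooperating-majority"),
                       cp_parameters(0.64, 0.45, 0.22, 0.12, 0.04)),
      dplyr::bind_cols(tibble::tibble(condition = "defecting-majority"),
                       cp_parameters(0.44, 0.35, 0.15, 0.05, 0.06))
    )
  }
}

#' Simulate the Prisoner's Dilemma experiment with costly punishment
#'
#' Generates one trial record per participant and trial. Each participant
#' receives a shuffled partner schedule with exactly
#' `round(rate * trials)` cooperation trials under the default exact
#' policy (or i.i.d. Bernoulli partner moves under `schedule =
#' "bernoulli"`). The participant cooperates with probability `C`
#' independently of the scheduled partner move; punishment follows the
#' model tree of the realized cell (outcome-specific process first, then
#' the unspecific bias); a punishing participant invests 1, 2 or 3 points
#' uniformly, deducting 10, 20 or 30 points from the partner. When the
#' design says so, partners always fine the participant's unilateral
#' defection by a uniform 10/20/30 points. The account ledger starts at the
#' endowment and accumulates game payoffs minus punishment costs and fines.
#'
#' @param design A design tibble (see [condition_design()],
#'   [experiment_design()]).
#' @param params A parameter table with a `condition` column matching the
#'   design (see [default_true_parameters()]).
#' @param seed Integer seed; identical seeds yield identical trial tables.
#' @param schedule `"exact"` (default) or `"bernoulli"` partner schedule
#'   policy.
#' @return A tibble with one row per participant x trial: `participant_id`,
#'   `condition`, `trial`, `partner_decision`, `participant_decision`,
#'   `punish_investment` (0-3), `partner_fine` (0/10/20/30),
#'   `payoff_delta`, `balance`.
#' @examples
#' trials <- simulate_experiment(experiment_design("exp2"),
#'   default_true_parameters("exp2"), seed = 1)
#' dplyr::count(trials, condition, partner_decision)
#' @export
simulate_experiment <- function(design, params, seed,
                                schedule = c("exact", "bernoulli")) {
  schedule <- match.arg(schedule)
  stopifnot(is.data.frame(design), nrow(design) >= 1L)
  ptab <- as_param_table(params, design$condition)
  local_rng(seed, {
    out <- purrr::map(seq_len(nrow(design)), function(i) {
      simulate_condition(design[i, ], ptab[ptab$condition ==
                                             design$condition[i], ],
                         schedule)
    })
    dplyr::bind_rows(out)
  })
}

simulate_condition <- function(d, prow, schedule) {
  n <- d$n_participants
  t <- d$trials
  theta <- as_param_vector(prow[setdiff(names(prow), "condition")])
  C <- theta[["C"]]; b <- theta[["b"]]
  if (schedule == "exact") {
    n_coop <- d$partner_coop_rate * t
    if (abs(n_coop - round(n_coop)) > 1e-9) {
      abort(sprintf(
        paste0("partner_coop_rate * trials = %g is not an integer; use ",
               "schedule = \"bernoulli\" for non-exact designs."), n_coop),
        class = "coopunish_config_error")
    }
    n_coop <- as.integer(round(n_coop))
    base <- rep(c("cooperate", "defect"), c(n_coop, t - n_coop))
    partner <- as.vector(vapply(seq_len(n), function(i) sample(base),
                                character(t)))
  } else {
    partner <- ifelse(rbinom(n * t, 1L, d$partner_coop_rate) == 1L,
                      "cooperate", "defect")
  }
  participant <- ifelse(rbinom(n * t, 1L, C) == 1L, "cooperate", "defect")
  # outcome-specific punishment probability of the realized cell
  p_spec <- dplyr::case_when(
    participant == "cooperate" & partner == "defect" ~ theta[["p_moral"]],
    participant == "defect" & partner == "defect" ~ theta[["p_hypocritical"]],
    participant == "defect" & partner == "cooperate" ~ theta[["p_antisocial"]],
    TRUE ~ 0
  )
  punished <- rbinom(n * t, 1L, p_spec) == 1L | rbinom(n * t, 1L, b) == 1L
  investment <- ifelse(punished, sample(1:3, n * t, replace = TRUE), 0L)
  unilateral_defection <- participant == "defect" & partner == "cooperate"
  fine <- if (d$partner_punishes_defection) {
    ifelse(unilateral_defection, sample(c(10L, 20L, 30L), n * t,
                                        replace = TRUE), 0L)
  } else {
    rep(0L, n * t)
  }
  delta <- apply_payoffs(participant, partner, investment, fine)
  tib <- tibble::tibble(
    participant_id = paste0(d$condition, "-",
                            rep(seq_len(n), each = t)),
    condition = d$condition,
    trial = rep(seq_len(t), times = n),
    partner_decision = partner,
    participant_decision = participant,
    punish_investment = as.integer(investment),
    partner_fine = as.integer(fine),
    payoff_delta = delta
  )
  tib$balance <- d$endowment + as.vector(
    apply(matrix(delta, nrow = t), 2L, cumsum))
  tib
}

#' Per-trial payoff delta for the participant
#'
#' The Prisoner's Dilemma payoff (mutual cooperation +10 each, mutual
#' defection 0, a defector gains +20 against a cooperator who loses 10)
#' minus the participant's own punishment investment and any fine received
#' from the partner.
#'
#' @param participant,partner `"cooperate"` or `"defect"` (vectorized).
#' @param investment Points invested in punishing the partner (0-3).
#' @param fine Points deducted by the partner's punishment (0/10/20/30).
#' @return Numeric payoff delta(s).
#' @examples
#' apply_payoffs("cooperate", "defect", investment = 2, fine = 0)  # -12
#' @export
apply_payoffs <- function(participant, partner, investment = 0, fine = 0) {
  ok <- c("cooperate", "defect")
  if (!all(participant %in% ok) || !all(partner %in% ok)) {
    abort("Decisions must be \"cooperate\" or \"defect\".")
  }
  stopifnot(all(investment %in% 0:3), all(fine %in% c(0, 10, 20, 30)))
  game <- dplyr::case_when(
    participant == "cooperate" & partner == "cooperate" ~ 10,
    participant == "defect" & partner == "defect" ~ 0,
    participant == "defect" & partner == "cooperate" ~ 20,
    TRUE ~ -10
  )
  game - investment - fine
}

#' Aggregate trial records into category counts
#'
#' Classifies every trial by condition, partner tree, participant decision
#' and whether the participant punished (any positive investment), and
#' tallies the eight model categories per condition. Totals are conserved:
#' the counts sum to the number of trial records.
#'
#' @param trials A trial table as produced by [simulate_experiment()] (or
#'   loaded via [read_trials()]).
#' @param conditions Optional expected condition labels; an unknown label
#'   in the data raises an error listing the labels seen.
#' @return A counts tibble in frozen category order.
#' @export
aggregate_counts <- function(trials, conditions = NULL) {
  need <- c("condition", "partner_decision", "participant_decision",
            "punish_investment")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(trials) == 0L) {
    return(category_counts(
      tibble::tibble(condition = character(), partner = character(),
                     decision = character(), punished = character(),
                     count = integer()),
      conditions = conditions %||% character()
    ))
  }
  tallied <- dplyr::count(
    trials,
    condition = as.character(.data$condition),
    partner = .data$partner_decision,
    decision = .data$participant_decision,
    punished = ifelse(.data$punish_investment > 0, "yes", "no"),
    name = "count"
  )
  category_counts(tallied, conditions = conditions)
}

#' Draw category counts directly from the model
#'
#' Samples the eight category counts per condition from the two
#' tree-conditional multinomials, given true parameters and per-tree
#' totals. This is the fast generative route used in Monte-Carlo
#' calibration studies; [simulate_experiment()] is the full trial-level
#' generator.
#'
#' @param params Parameter table (`condition` plus the five parameters).
#' @param totals A tibble with columns `condition`, `partner`
#'   (`"cooperate"`/`"defect"`) and `total`, or a design tibble (totals are
#'   then `n_participants * trials * rate`).
#' @param seed Integer seed.
#' @return A counts tibble.
#' @export
simulate_counts <- function(params, totals, seed = NULL) {
  if ("n_participants" %in% names(totals)) totals <- design_totals(totals)
  conditions <- unique(totals$condition)
  ptab <- as_param_table(params, conditions)
  grid <- tidyr::expand_grid(condition = conditions, cp_category_grid())
  local_rng(seed, {
    counts <- integer(0)
    for (cond in conditions) {
      theta <- as_param_vector(
        ptab[ptab$condition == cond, setdiff(names(ptab), "condition")])
      p <- prob_vector(theta)
      draw <- function(tree_partner, idx) {
        tot <- totals$total[totals$condition == cond &
                              totals$partner == tree_partner]
        if (!length(tot) || tot == 0) return(rep(0L, 4L))
        as.integer(rmultinom(1L, tot, p[idx]))
      }
      counts <- c(counts, draw("defect", 1:4), draw("cooperate", 5:8))
    }
    grid$count <- counts
    category_counts(grid, conditions)
  })
}

# Per-tree totals implied by an exact-schedule design.
design_totals <- function(design) {
  dplyr::bind_rows(
    tibble::tibble(condition = design$condition, partner = "defect",
                   total = design$n_participants * design$trials *
                     (1 - design$partner_coop_rate)),
    tibble::tibble(condition = design$condition, partner = "cooperate",
                   total = design$n_participants * design$trials *
                     design$partner_coop_rate)
  )
}

#' Read and write trial tables
#'
#' Trial records are stored as tab-delimited text with the documented
#' header (one row per participant x trial). `read_trials()` accepts an
#' optional column mapping (named character vector,
#' `c(our_name = "their_name")`) so external exports with different column
#' names can be loaded.
#'
#' @param trials A trial table.
#' @param path File path.
#' @param mapping Optional named character vector mapping package column
#'   names to columns present in the file.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` a
#'   trial tibble.
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
  if (!is.null(mapping)) {
    bad <- setdiff(unname(mapping), names(df))
    if (length(bad)) {
      abort(paste0("Mapped column(s) not in file: ",
                   paste(bad, collapse = ", ")))
    }
    df <- dplyr::rename(df, !!!rlang::set_names(unname(mapping),
                                                names(mapping)))
  }
  df
}

#' Read and write a simulation configuration
#'
#' The generator configuration (condition designs, true parameters, seed,
#' schedule policy) round-trips through a YAML file so simulated datasets
#' are reproducible from a small text artifact.
#'
#' @param design,params,seed,schedule As for [simulate_experiment()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` a list with elements `design`, `params`, `seed`,
#'   `schedule`.
#' @export
write_sim_config <- function(design, params, seed, schedule = "exact",
                             path) {
  yaml::write_yaml(
    list(design = as.data.frame(design), params = as.data.frame(params),
         seed = seed, schedule = schedule),
    path
  )
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    design = tibble::as_tibble(as.data.frame(cfg$design)),
    params = tibble::as_tibble(as.data.frame(cfg$params)),
    seed = cfg$seed,
    schedule = cfg$schedule %||% "exact"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
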