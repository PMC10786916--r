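test_that("the payoff ledger reproduces the game's payoff structure", {
  expect_equal(apply_payoffs("cooperate", "cooperate"), 10)
  expect_equal(apply_payoffs("defect", "defect"), 0)
  expect_equal(apply_payoffs("defect", "cooperate"), 20)
  expect_equal(apply_payoffs("cooperate", "defect"), -10)
  # worked trial: cooperating participant, defecting partner, invests 2
  # points (a 20-point fine to the partner)
  expect_equal(apply_payoffs("cooperate", "defect", investment = 2), -12)
  expect_equal(apply_payoffs("defect", "cooperate", investment = 0,
                             fine = 20), 0)
  # PD ordering: T > R > P > S
  expect_true(20 > 10 && 10 > 0 && 0 > -10)
  expect_error(apply_payoffs("coop", "defect"), "cooperate")
})

test_that("identical seeds give byte-identical trial tables", {
  d <- experiment_design("exp1")
  p <- default_true_parameters("exp1")
  t1 <- simulate_experiment(d, p, seed = 99)
  t2 <- simulate_experiment(d, p, seed = 99)
  t3 <- simulate_experiment(d, p, seed = 100)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("the exact schedule gives every participant the designed split", {
  trials <- simulate_experiment(experiment_design("exp1"),
                                default_true_parameters("exp1"), seed = 7)
  per_part <- dplyr::summarise(
    dplyr::group_by(trials, condition, participant_id),
    n_coop = sum(partner_decision == "cooperate"),
    n = dplyr::n(), .groups = "drop")
  expect_true(all(per_part$n == 25L))
  expect_true(all(per_part$n_coop[
    per_part$condition == "cooperating-majority"] == 15L))
  expect_true(all(per_part$n_coop[
    per_part$condition == "defecting-majority"] == 10L))
  # tree totals: 278 x {15 coop, 10 defect} and 266 x {10 coop, 15 defect}
  tt <- tree_totals(aggregate_counts(trials))
  expect_equal(tt$total[tt$condition == "cooperating-majority" &
                          tt$partner == "cooperate"], 278L * 15L)
  expect_equal(tt$total[tt$condition == "cooperating-majority" &
                          tt$partner == "defect"], 278L * 10L)
  expect_equal(tt$total[tt$condition == "defecting-majority" &
                          tt$partner == "cooperate"], 266L * 10L)
  expect_equal(tt$total[tt$condition == "defecting-majority" &
                          tt$partner == "defect"], 266L * 15L)
})

test_that("non-integer exact schedules error with a pointer to bernoulli", {
  d <- condition_design("odd", partner_coop_rate = 0.55,
                        n_participants = 10)
  p <- dplyr::bind_cols(tibble::tibble(condition = "odd"),
                        cp_parameters(0.5))
  expect_error(simulate_experiment(d, p, seed = 1), "bernoulli",
               class = "coopunish_config_error")
  tr <- simulate_experiment(d, p, seed = 1, schedule = "bernoulli")
  expect_equal(nrow(tr), 250L)
})

test_that("punishment investments map to fines and the ledger balances", {
  trials <- simulate_experiment(experiment_design("exp1"),
                                default_true_parameters("exp1"), seed = 13)
  expect_true(all(trials$punish_investment %in% 0:3))
  # Exp. 1 partners always fine unilateral defection, never anything else
  unilateral <- trials$participant_decision == "defect" &
    trials$partner_decision == "cooperate"
  expect_true(all(trials$partner_fine[unilateral] %in% c(10L, 20L, 30L)))
  expect_true(all(trials$partner_fine[!unilateral] == 0L))
  # ledger: balance = endowment + cumulative deltas
  one <- trials[trials$participant_id == trials$participant_id[1L], ]
  expect_equal(one$balance, 150 + cumsum(one$payoff_delta))
  # Exp. 2: no partner punishment at all
  t2 <- simulate_experiment(experiment_design("exp2"),
                            default_true_parameters("exp2"), seed = 13)
  expect_true(all(t2$partner_fine == 0L))
})

test_that("aggregation conserves totals and validates labels", {
  empty <- aggregate_counts(tibble::tibble(
    condition = character(), partner_decision = character(),
    participant_decision = character(), punish_investment = integer()))
  expect_equal(sum(empty$count), 0L)

  trials <- simulate_experiment(
    condition_design("solo", 0.6, n_participants = 1,
                     partner_punishes_defection = TRUE),
    dplyr::bind_cols(tibble::tibble(condition = "solo"),
                     cp_parameters(0.5, 0.5, 0.5, 0.5, 0.2)),
    seed = 3)
  counts <- aggregate_counts(trials)
  expect_equal(sum(counts$count), 25L)

  expect_error(aggregate_counts(trials, conditions = c("x", "y")),
               "solo")
})

test_that("simulated cell frequencies converge to the model's branch probabilities", {
  # one condition, 4000 participants x 25 trials = 1e5 decisions
  params <- cp_parameters(0.6, 0.5, 0.3, 0.2, 0.1)
  design <- condition_design("big", 0.6, n_participants = 4000)
  trials <- simulate_experiment(design, dplyr::bind_cols(
    tibble::tibble(condition = "big"), params), seed = 2024)
  counts <- aggregate_counts(trials)
  probs <- category_probabilities(params)
  joined <- dplyr::left_join(counts, probs,
                             by = c("partner", "decision", "punished"))
  joined <- dplyr::mutate(
    dplyr::group_by(joined, partner),
    tree_total = sum(count), freq = count / tree_total)
  se <- sqrt(joined$probability * (1 - joined$probability) /
               joined$tree_total)
  expect_true(all(abs(joined$freq - joined$probability) <= 3 * se))
})

test_that("trial tables, counts and configs round-trip through text files", {
  trials <- simulate_experiment(
    condition_design("rt", 0.6, 5), dplyr::bind_cols(
      tibble::tibble(condition = "rt"), cp_parameters(0.6, 0.4, b = 0.1)),
    seed = 21)
  tfile <- withr::local_tempfile(fileext = ".tsv")
  write_trials(trials, tfile)
  back <- read_trials(tfile)
  expect_equal(as.data.frame(back), as.data.frame(trials))

  counts <- aggregate_counts(trials)
  for (ext in c(".tsv", ".json")) {
    cfile <- withr::local_tempfile(fileext = ext)
    write_counts(counts, cfile)
    expect_equal(as.data.frame(read_counts(cfile)), as.data.frame(counts))
  }

  # column mapping for externally produced trial exports
  renamed <- dplyr::rename(trials, cond = "condition",
                           invest = "punish_investment")
  tfile2 <- withr::local_tempfile(fileext = ".tsv")
  write_trials(renamed, tfile2)
  remapped <- read_trials(tfile2, mapping = c(
    condition = "cond", punish_investment = "invest"))
  expect_true(all(c("condition", "punish_investment") %in% names(remapped)))

  yfile <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(experiment_design("exp2"),
                   default_true_parameters("exp2"), seed = 5, path = yfile)
  cfg <- read_sim_config(yfile)
  expect_equal(cfg$seed, 5)
  expect_equal(as.data.frame(cfg$design),
               as.data.frame(experiment_design("exp2")))
  redo <- simulate_experiment(cfg$design, cfg$params, seed = cfg$seed,
                              schedule = cfg$schedule)
  expect_identical(redo, simulate_experiment(experiment_design("exp2"),
                                             default_true_parameters("exp2"),
                                             seed = 5))
})
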