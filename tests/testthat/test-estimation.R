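test_that("log-likelihood follows the product-multinomial conventions", {
  m1 <- cp_model("cond")
  # empty data: empty product
  expect_identical(cp_loglik(m1, rep(0.5, 5), counts_from_vector(rep(0, 8))),
                   0)
  # a cell with probability one contributes log(1) = 0
  theta_cert <- c(1, 1, 0.5, 0.5, 0.5)  # C=1, p_moral=1
  expect_identical(
    cp_loglik(m1, theta_cert, counts_from_vector(c(10, 0, 0, 0, 0, 0, 0, 0))),
    0)
  # hand computation: (5,5,0,0) in the partner-defects tree at
  # C=1, p_moral=0.5, b=0 puts probability 1/2 on each observed cell
  expect_equal(
    cp_loglik(m1, c(1, 0.5, 0.5, 0.5, 0),
              counts_from_vector(c(5, 5, 0, 0, 0, 0, 0, 0))),
    10 * log(0.5))
  # positive count on a zero-probability cell signals boundary misfit
  expect_identical(
    cp_loglik(m1, c(1, 0.5, 0.5, 0.5, 0),
              counts_from_vector(c(5, 5, 1, 0, 0, 0, 0, 0))),
    -Inf)
  expect_error(cp_loglik(m1, c(1.5, 0.5, 0.5, 0.5, 0.5),
                         counts_from_vector(rep(1, 8))),
               class = "coopunish_domain_error")
})

test_that("a perfectly model-consistent table is fit exactly", {
  fit <- cp_fit(perfect_counts(), seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$g_squared, 1e-6)
  est <- tidy(fit)
  truth <- unlist(perfect_params())
  expect_equal(stats::setNames(est$estimate, est$parameter),
               truth[est$parameter], tolerance = 1e-6)
})

test_that("the optimizer reproduces the closed-form MLE on unrestricted fits", {
  withr::with_seed(202, {
    for (i in 1:10) {
      counts <- random_interior_counts()
      fit <- cp_fit(counts, seed = i, se = "none")
      n <- coopunish:::as_count_matrix(counts, "cond")
      oracle <- coopunish:::closed_form_mle(n[1L, ])
      est <- tidy(fit)
      expect_equal(stats::setNames(est$estimate, est$parameter),
                   oracle[est$parameter], tolerance = 1e-6)
    }
  })
})

test_that("restriction tests are non-negative and vanish under equality", {
  counts <- dplyr::bind_rows(
    perfect_counts("a"),
    perfect_counts("b")
  )
  # both conditions identical: every restriction already holds
  for (par in c("C", "p_moral", "b")) {
    rt <- cp_test_restriction(counts, parameter = par, seed = 5)
    expect_lt(rt$delta_g_squared, 1e-6)
    expect_gt(rt$p_value, 0.999)
    expect_identical(rt$df, 1L)
  }
  # and on heterogeneous data every restriction still satisfies nesting
  withr::with_seed(303, {
    counts2 <- dplyr::bind_rows(
      random_interior_counts(condition = "a"),
      random_interior_counts(condition = "b")
    )
    base <- cp_fit(counts2, cp_model(c("a", "b")), seed = 1, se = "none")
    for (par in coopunish:::cp_param_names()) {
      rt <- cp_test_restriction(counts2, parameter = par, base_fit = base,
                                seed = 2)
      expect_gte(rt$delta_g_squared, 0)
      expect_equal(rt$w, sqrt(rt$delta_g_squared / sum(counts2$count)))
    }
  })
})

test_that("the cross-parameter restriction equates cells across conditions", {
  withr::with_seed(404, {
    counts <- dplyr::bind_rows(
      random_interior_counts(condition = "a"),
      random_interior_counts(condition = "b")
    )
  })
  rt <- cp_test_restriction(
    counts, pair = list(c("a", "p_moral"), c("b", "p_antisocial")),
    seed = 3)
  expect_identical(rt$df, 1L)
  rest <- tidy(rt$restricted_fit)
  expect_equal(
    rest$estimate[rest$condition == "a" & rest$parameter == "p_moral"],
    rest$estimate[rest$condition == "b" & rest$parameter == "p_antisocial"])
})

test_that("information-based standard errors match binomial closed forms", {
  counts <- perfect_counts()
  fit <- cp_fit(counts, seed = 1)
  expect_identical(fit$se_method, "information")
  est <- tidy(fit)
  n_total <- sum(counts$count)
  # the cooperation block of the likelihood is a pure binomial in C
  se_C <- est$std.error[est$parameter == "C"]
  expect_equal(se_C, sqrt(0.6 * 0.4 / n_total), tolerance = 1e-6)
  # b is a binomial rate of the mutual-cooperation cell (n = 240)
  se_b <- est$std.error[est$parameter == "b"]
  expect_equal(se_b, sqrt(0.2 * 0.8 / 240), tolerance = 1e-6)
})

test_that("bootstrap and information standard errors agree at large n", {
  withr::with_seed(505, {
    counts <- simulate_counts(
      cp_parameters(0.6, 0.5, 0.35, 0.25, 0.15),
      tibble::tibble(condition = "cond", partner = c("defect", "cooperate"),
                     total = 5000L))
  })
  info <- cp_fit(counts, seed = 1, se = "information")
  boot <- cp_fit(counts, seed = 1, se = "bootstrap", boot_reps = 200L)
  expect_identical(boot$se_method, "bootstrap")
  rel <- abs(boot$se_free - info$se_free) / info$se_free
  expect_true(all(rel < 0.1))
})

test_that("boundary estimates are flagged and fall back to the bootstrap", {
  # no punishment at all: b and the punishment parameters sit at zero
  counts <- counts_from_vector(c(0, 100, 0, 100, 0, 120, 0, 80))
  fit <- cp_fit(counts, seed = 2, boot_reps = 50L)
  expect_true(any(fit$boundary))
  expect_identical(fit$se_method, "bootstrap")
  expect_true(all(is.finite(fit$se_free)))
})

test_that("the best objective is stable across reruns with different seeds", {
  withr::with_seed(606, counts <- random_interior_counts())
  objectives <- vapply(1:4, function(s) {
    cp_fit(counts, seed = s * 11L, se = "none")$logLik
  }, numeric(1))
  expect_lt(max(objectives) - min(objectives), 1e-6)
})

test_that("empty trees warn and contribute nothing", {
  counts <- counts_from_vector(c(30, 30, 20, 20, 0, 0, 0, 0))
  expect_warning(fit <- cp_fit(counts, seed = 1, se = "none"),
                 "Empty tree")
  # cooperation is then a pure binomial on the partner-defects tree
  est <- tidy(fit)
  expect_equal(est$estimate[est$parameter == "C"], 0.6, tolerance = 1e-6)
})
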