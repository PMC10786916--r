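#' Product-multinomial log-likelihood
#'
#' The model is fit to tree-conditional counts: each of the two trees per
#' condition is a multinomial over its four categories, conditioned on the
#' number of trials with that partner behaviour. The log-likelihood (up to
#' the multinomial constant) is `sum n_i * log p_i` with the convention
#' `0 * log 0 = 0`; a category with positive count but zero model
#' probability yields `-Inf` (a boundary misfit, not an error).
#'
#' @param model A `cp_model`.
#' @param theta Numeric vector of free parameters in `[0, 1]`, one per free
#'   index of the sharing map.
#' @param counts A counts table (see [category_counts()]).
#' @return The log-likelihood (real or `-Inf`).
#' @export
cp_loglik <- function(model, theta, counts) {
  stopifnot(inherits(model, "cp_model"))
  if (length(theta) != n_free_parameters(model)) {
    abort(sprintf("Expected %d free parameters, got %d.",
                  n_free_parameters(model), length(theta)))
  }
  if (any(theta < 0 | theta > 1)) {
    abort("Free parameters must lie in [0, 1].",
          class = "coopunish_domain_error")
  }
  n <- as_count_matrix(counts, model$conditions)
  loglik_value(theta, n, sharing_matrix(model))
}

# Hot path: plain-vector log-likelihood.
loglik_value <- function(theta, n, M) {
  ll <- 0
  for (i in seq_len(nrow(n))) {
    p <- prob_vector(theta[M[i, ]])
    ni <- n[i, ]
    pos <- ni > 0L
    if (any(pos & p <= 0)) return(-Inf)
    ll <- ll + sum(ni[pos] * log(p[pos]))
  }
  ll
}

# Saturated log-likelihood: observed tree-conditional relative frequencies,
# same 0*log(0) = 0 convention; empty trees contribute nothing.
loglik_saturated <- function(n) {
  ll <- 0
  for (i in seq_len(nrow(n))) {
    for (tree in list(1:4, 5:8)) {
      ni <- n[i, tree]
      tot <- sum(ni)
      if (tot > 0L) {
        pos <- ni > 0L
        ll <- ll + sum(ni[pos] * log(ni[pos] / tot))
      }
    }
  }
  ll
}

# Jacobian of the 8 category probabilities with respect to the 5 condition
# parameters (C, p_moral, p_hypocritical, p_antisocial, b), frozen order.
prob_jacobian <- function(theta) {
  C <- theta[[1L]]; pm <- theta[[2L]]; ph <- theta[[3L]]
  pa <- theta[[4L]]; b <- theta[[5L]]
  J <- matrix(0, nrow = 8L, ncol = 5L)
  J[1L, ] <- c(pm + (1 - pm) * b, C * (1 - b), 0, 0, C * (1 - pm))
  J[2L, ] <- c((1 - pm) * (1 - b), -C * (1 - b), 0, 0, -C * (1 - pm))
  J[3L, ] <- c(-(ph + (1 - ph) * b), 0, (1 - C) * (1 - b), 0,
               (1 - C) * (1 - ph))
  J[4L, ] <- c(-(1 - ph) * (1 - b), 0, -(1 - C) * (1 - b), 0,
               -(1 - C) * (1 - ph))
  J[5L, ] <- c(b, 0, 0, 0, C)
  J[6L, ] <- c(1 - b, 0, 0, 0, -C)
  J[7L, ] <- c(-(pa + (1 - pa) * b), 0, 0, (1 - C) * (1 - b),
               (1 - C) * (1 - pa))
  J[8L, ] <- c(-(1 - pa) * (1 - b), 0, 0, -(1 - C) * (1 - b),
               -(1 - C) * (1 - pa))
  J
}

# Gradient of the negative log-likelihood with respect to the free
# parameters (probability scale). Zero-count cells contribute nothing.
grad_negll <- function(theta, n, M) {
  g <- numeric(length(theta))
  for (i in seq_len(nrow(n))) {
    th_i <- theta[M[i, ]]
    p <- prob_vector(th_i)
    ni <- n[i, ]
    ratio <- ifelse(ni > 0L, ni / pmax(p, 1e-300), 0)
    g_cond <- -drop(crossprod(prob_jacobian(th_i), ratio))
    for (j in 1:5) {  # duplicate indices within a condition must accumulate
      g[M[i, j]] <- g[M[i, j]] + g_cond[j]
    }
  }
  g
}

# Closed-form per-condition MLE of the unrestricted model. The likelihood
# factorizes into a cooperation binomial (C appears identically in both
# trees) and four conditional punish rates which map one-to-one onto
# (p_moral, p_hypocritical, p_antisocial, b):
#   b = punish rate in the mutual-cooperation cell,
#   P = (rate - b) / (1 - b) for the three specific cells, clipped to [0,1].
# Unidentified cells (empty denominators, b = 1) default to 0.5 — any value
# attains the same likelihood there.
closed_form_mle <- function(ncond_row) {
  n <- ncond_row
  rate <- function(x, tot) if (tot > 0) x / tot else 0.5
  total <- sum(n)
  C <- rate(n[1L] + n[2L] + n[5L] + n[6L], total)
  b <- rate(n[5L], n[5L] + n[6L])
  unbias <- function(r) {
    if (b >= 1) return(0.5)
    min(1, max(0, (r - b) / (1 - b)))
  }
  c(C = C,
    p_moral = unbias(rate(n[1L], n[1L] + n[2L])),
    p_hypocritical = unbias(rate(n[3L], n[3L] + n[4L])),
    p_antisocial = unbias(rate(n[7L], n[7L] + n[8L])),
    b = b)
}

# Informed start for the optimizer: closed-form per-condition values,
# averaged over cells that share a free index.
informed_start <- function(n, M) {
  per_cond <- t(apply(n, 1L, closed_form_mle))
  k <- max(M)
  theta <- numeric(k)
  for (j in seq_len(k)) {
    theta[j] <- mean(per_cond[M == j])
  }
  pmin(pmax(theta, 1e-4), 1 - 1e-4)
}

#' Fit the cooperation-and-punishment model by maximum likelihood
#'
#' Maximizes the product-multinomial log-likelihood over the model's free
#' parameters. Optimization runs on the log-odds scale (an unconstrained
#' transform of the unit interval) with multiple starting points: one
#' derived from the closed-form per-condition estimator plus random starts.
#' The goodness-of-fit statistic is
#' `G^2 = 2 * (logLik_saturated - logLik_model)`, asymptotically chi-square
#' with [degrees_of_freedom()] degrees of freedom under the model.
#'
#' @param counts A counts table (see [category_counts()]).
#' @param model A `cp_model`; defaults to the unrestricted base model over
#'   the conditions present in `counts`.
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Optional integer seed for the random starts (and a bootstrap
#'   fallback, if triggered).
#' @param se Standard-error method: `"information"` (inverse observed
#'   information, with automatic parametric-bootstrap fallback at boundary
#'   estimates or a singular information matrix), `"bootstrap"`, or
#'   `"none"`.
#' @param boot_reps Bootstrap replications for the fallback (default 200).
#'
#' @return An object of class `cp_fit`; see [tidy.cp_fit()] and
#'   [glance.cp_fit()] for tabular accessors.
#' @examples
#' trials <- simulate_experiment(experiment_design("exp2"),
#'   default_true_parameters(), seed = 42)
#' fit <- cp_fit(aggregate_counts(trials), seed = 1)
#' glance(fit)
#' @export
cp_fit <- function(counts, model = NULL, n_starts = 5L, seed = NULL,
                   se = c("information", "bootstrap", "none"),
                   boot_reps = 200L) {
  se <- match.arg(se)
  counts <- category_counts(counts)
  if (is.null(model)) model <- cp_model(unique(counts$condition))
  n <- as_count_matrix(counts, model$conditions)
  M <- sharing_matrix(model)
  tt <- tree_totals(counts)
  if (any(tt$total == 0L)) {
    warn(paste0("Empty tree(s): ",
                paste(paste(tt$condition[tt$total == 0L],
                            tt$partner[tt$total == 0L]), collapse = "; "),
                " — they contribute nothing to the fit."))
  }

  opt <- optimize_loglik(n, M, n_starts = n_starts, seed = seed)
  theta <- opt$theta
  ll <- opt$loglik
  g2 <- max(0, 2 * (loglik_saturated(n) - ll))
  df <- degrees_of_freedom(model)
  boundary <- theta < 1e-5 | theta > 1 - 1e-5

  fit <- structure(
    list(
      model = model, counts = counts, theta = theta,
      logLik = ll, g_squared = g2, df = df,
      p_value = chisq_p(g2, max(df, 1L)) * (df > 0L) + (df == 0L),
      converged = opt$converged, n_starts = n_starts,
      best_start_objective = -ll, boundary = boundary,
      se_free = rep(NA_real_, length(theta)), se_method = "none",
      n_obs = sum(n), seed = seed
    ),
    class = "cp_fit"
  )
  if (df == 0L) fit$p_value <- 1
  if (se != "none") fit <- add_standard_errors(fit, method = se,
                                               boot_reps = boot_reps)
  fit
}

optimize_loglik <- function(n, M, n_starts = 5L, seed = NULL,
                            rel_tol = 1e-12) {
  k <- max(M)
  negll <- function(x) -loglik_value(stats::plogis(x), n, M)
  # chain rule through the logistic transform: d theta / d x = theta(1-theta)
  negll_grad <- function(x) {
    theta <- stats::plogis(x)
    grad_negll(theta, n, M) * theta * (1 - theta)
  }
  starts <- local_rng(seed, {
    rand <- matrix(runif((max(n_starts, 1L) - 1L) * k, 0.05, 0.95),
                   ncol = k)
    rbind(informed_start(n, M), rand)
  })
  best <- NULL
  converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    res <- suppressWarnings(
      nlminb(stats::qlogis(starts[s, ]), negll, gradient = negll_grad,
             control = list(rel.tol = rel_tol, eval.max = 2000L,
                            iter.max = 1000L))
    )
    if (is.null(best) || res$objective < best$objective) best <- res
    if (res$convergence == 0L) converged <- TRUE
  }
  list(theta = stats::plogis(best$par), loglik = -best$objective,
       converged = converged)
}

# Runs code with a temporary RNG state when seed is given; leaves the
# global stream untouched either way unless seed is NULL.
local_rng <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Standard errors for the free parameters: inverse observed information
# (Hessian of the negative log-likelihood at the MLE, probability scale),
# or a parametric bootstrap when the estimate is on the boundary or the
# information matrix is not invertible.
add_standard_errors <- function(fit, method = "information",
                                boot_reps = 200L) {
  n <- as_count_matrix(fit$counts, fit$model$conditions)
  M <- sharing_matrix(fit$model)
  use_boot <- method == "bootstrap" || any(fit$boundary)
  if (!use_boot) {
    clamp <- function(th) pmin(pmax(th, 1e-12), 1 - 1e-12)
    H <- try(optimHess(fit$theta,
                       function(th) -loglik_value(clamp(th), n, M),
                       function(th) grad_negll(clamp(th), n, M),
                       control = list(ndeps = rep(1e-6, length(fit$theta)))),
             silent = TRUE)
    V <- if (inherits(H, "try-error")) NULL else try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && !is.null(V) && all(diag(V) >= 0)) {
      fit$se_free <- sqrt(diag(V))
      fit$se_method <- "information"
      return(fit)
    }
    use_boot <- TRUE
  }
  if (use_boot) {
    fit$se_free <- bootstrap_se(fit, n, M, boot_reps = boot_reps)
    fit$se_method <- "bootstrap"
  }
  fit
}

bootstrap_se <- function(fit, n, M, boot_reps = 200L) {
  k <- max(M)
  draws <- local_rng(if (is.null(fit$seed)) NULL else fit$seed + 1L, {
    t(vapply(seq_len(boot_reps), function(r) {
      nb <- n
      for (i in seq_len(nrow(n))) {
        p <- prob_vector(fit$theta[M[i, ]])
        for (tree in list(1:4, 5:8)) {
          tot <- sum(n[i, tree])
          nb[i, tree] <- if (tot > 0L) {
            as.integer(rmultinom(1L, tot, p[tree]))
          } else 0L
        }
      }
      optimize_loglik(nb, M, n_starts = 2L, seed = NULL)$theta
    }, numeric(k)))
  })
  apply(draws, 2L, stats::sd)
}

#' @export
print.cp_fit <- function(x, ...) {
  cat("<cp_fit> ", length(x$model$conditions), " condition(s), ",
      n_free_parameters(x$model), " free parameter(s)\n", sep = "")
  cat(sprintf("  G^2(%d) = %.2f, p = %.3f%s\n", x$df, x$g_squared,
              x$p_value,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a fitted cooperation-and-punishment model
#'
#' @param x A `cp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (condition, parameter): `estimate`,
#'   `std.error`, `boundary` (whether the estimate hit 0/1).
#' @method tidy cp_fit
#' @export
tidy.cp_fit <- function(x, ...) {
  M <- sharing_matrix(x$model)
  sh <- x$model$sharing
  tibble::tibble(
    condition = sh$condition,
    parameter = sh$parameter,
    estimate = x$theta[sh$index],
    std.error = x$se_free[sh$index],
    boundary = x$boundary[sh$index]
  )
}

#' One-row fit summary
#'
#' @param x A `cp_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `g.squared`, `df`, `p.value`,
#'   `converged`, `n.starts`, `n.obs`, `se.method`.
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, g.squared = x$g_squared, df = x$df,
    p.value = x$p_value, converged = x$converged,
    n.starts = x$n_starts, n.obs = x$n_obs, se.method = x$se_method
  )
}

#' Expected counts under a fitted model
#'
#' @param object A `cp_fit`.
#' @param ... Unused.
#' @return A counts-shaped tibble with an `expected` column.
#' @export
fitted_counts <- function(object, ...) {
  stopifnot(inherits(object, "cp_fit"))
  n <- as_count_matrix(object$counts, object$model$conditions)
  M <- sharing_matrix(object$model)
  out <- object$counts
  expected <- numeric(0)
  for (i in seq_len(nrow(n))) {
    p <- prob_vector(object$theta[M[i, ]])
    e <- c(p[1:4] * sum(n[i, 1:4]), p[5:8] * sum(n[i, 5:8]))
    expected <- c(expected, e)
  }
  out$expected <- expected
  out
}
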