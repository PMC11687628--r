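#' Parametric bootstrap of regime optima under a fitted model
#'
#' For each replicate, tip data are simulated on the same tree and painting
#' under the fitted model's maximum-likelihood estimates, the same model is
#' refitted (starting from those estimates), and the per-regime theta
#' estimates are recorded. Replicates whose refit fails are redrawn with a
#' fresh derived seed; more than 20% failures aborts with diagnostics.
#'
#' @param tree,regimes tree and painting the model was fitted on.
#' @param fit an `ou_fit` from [fit_ou_model()].
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer master seed; replicate r draws with seed
#'   `seed + r` (redraws continue past `n_reps`).
#' @param config fitting configuration for the refits; defaults to a light
#'   configuration polishing only the MLE start.
#' @return a `bootstrap_distribution`: list with `theta` (n_reps x regimes
#'   matrix of bootstrap estimates), `model`, `n_reps`, `seeds` used, and
#'   `n_redraws`.
#' @export
parametric_bootstrap <- function(tree, regimes, fit, n_reps = 100, seed = 1,
                                 config = NULL) {
  stopifnot(inherits(fit, "ou_fit"), n_reps >= 1)
  if (is.null(config)) {
    config <- ou_fit_config(n_alpha_starts = 2, n_sigma_starts = 2,
                            n_polish = 1, root_mode = fit$root_mode)
  }
  params <- list(theta = fit$theta, alpha = fit$alpha, sigma2 = fit$sigma2)
  start <- if (fit$spec$is_ou) {
    list(alpha = fit$alpha, sigma2 = fit$sigma2)
  } else list(sigma2 = fit$sigma2)

  nt <- length(fit$theta)
  theta_mat <- matrix(NA_real_, n_reps, nt,
                      dimnames = list(NULL, names(fit$theta)))
  seeds <- integer(n_reps)
  n_fail <- 0L
  r <- 0L
  draw <- 0L
  max_fail <- max(1, ceiling(0.2 * n_reps))
  errors <- character(0)
  while (r < n_reps) {
    draw <- draw + 1L
    rep_seed <- seed + draw
    res <- tryCatch({
      y <- simulate_tips(tree, regimes, fit$model, params, seed = rep_seed,
                         root_mode = fit$root_mode)
      refit <- fit_ou_model(tree, regimes, y, fit$model, config, start = start,
                            se = FALSE, warn_bound = FALSE)
      as.numeric(refit$theta)
    }, error = function(e) e)
    if (inherits(res, "error") || any(!is.finite(res))) {
      n_fail <- n_fail + 1L
      if (inherits(res, "error")) errors <- c(errors, conditionMessage(res))
      if (n_fail > max_fail) {
        stop(sprintf(
          "parametric bootstrap: %d of %d draws failed to refit (last: %s)",
          n_fail, draw, utils::tail(errors, 1)), call. = FALSE)
      }
      next
    }
    r <- r + 1L
    theta_mat[r, ] <- res
    seeds[r] <- rep_seed
  }
  structure(list(theta = theta_mat, model = fit$model, n_reps = n_reps,
                 seeds = seeds, n_redraws = n_fail),
            class = "bootstrap_distribution")
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: %s, %d replicates (%d redraws)\n",
              x$model, x$n_reps, x$n_redraws))
  print(apply(x$theta, 2, stats::quantile, c(0.025, 0.5, 0.975)), digits = 4)
  invisible(x)
}

#' Compare two bootstrap theta distributions
#'
#' Two-sided Mann-Whitney test between the bootstrap distributions of the
#' optima of two regimes.
#'
#' @param boot a `bootstrap_distribution` with at least two regime columns.
#' @param regimes which two columns to compare (defaults to the first two).
#' @return a `mann_whitney` result.
#' @export
compare_bootstrap_theta <- function(boot, regimes = NULL) {
  stopifnot(inherits(boot, "bootstrap_distribution"))
  if (ncol(boot$theta) < 2) {
    stop("fitted model has a single theta: nothing to compare", call. = FALSE)
  }
  if (is.null(regimes)) regimes <- colnames(boot$theta)[1:2]
  mann_whitney(boot$theta[, regimes[1]], boot$theta[, regimes[2]])
}
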