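# Internal: map a model's free nonlinear parameters (log scale) to per-regime
# alpha / sigma^2 vectors.
phi_to_rates <- function(phi, spec, n_regimes) {
  i <- 0
  if (spec$is_ou) {
    na <- if (spec$alpha_by_regime) n_regimes else 1
    alpha <- exp(phi[seq_len(na)])
    if (na == 1) alpha <- rep(alpha, n_regimes)
    i <- na
  } else {
    alpha <- rep(0, n_regimes)
  }
  ns <- if (spec$sigma_by_regime) n_regimes else 1
  sigma2 <- exp(phi[i + seq_len(ns)])
  if (ns == 1) sigma2 <- rep(sigma2, n_regimes)
  list(alpha = alpha, sigma2 = sigma2)
}

# Internal: profiled Gaussian log-likelihood at one nonlinear parameter
# point. theta (or the BM root mean) is profiled out by GLS.
ou_profile_loglik <- function(phi, pre, spec, y, root_mode) {
  rates <- phi_to_rates(phi, spec, pre$n_regimes)
  if (!spec$is_ou) root_mode <- "fixed"  # BM has no stationary distribution
  mom <- try(ou_moments(pre, rates$alpha, rates$sigma2, root_mode), silent = TRUE)
  if (inherits(mom, "try-error")) return(list(loglik = -Inf))
  W <- if (spec$theta_by_regime) mom$W else matrix(1, pre$ntip, 1)
  # regimes absent from the painting contribute no weight; their theta is
  # inestimable (NA) and the fit collapses to the present-regime model
  nz <- colSums(abs(W)) > 0
  L <- try(chol(mom$V), silent = TRUE)
  if (inherits(L, "try-error")) return(list(loglik = -Inf))
  Liy <- backsolve(L, y, transpose = TRUE)
  LiW <- backsolve(L, W[, nz, drop = FALSE], transpose = TRUE)
  xtx <- crossprod(LiW)
  theta_nz <- try(solve(xtx, crossprod(LiW, Liy)), silent = TRUE)
  if (inherits(theta_nz, "try-error")) return(list(loglik = -Inf))
  resid <- Liy - LiW %*% theta_nz
  n <- pre$ntip
  ll <- -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(resid^2)
  theta <- rep(NA_real_, ncol(W))
  theta[nz] <- as.numeric(theta_nz)
  list(loglik = as.numeric(ll), theta = theta,
       alpha = rates$alpha, sigma2 = rates$sigma2, W = W, V = mom$V)
}

#' Log-likelihood of tip data under a fully specified trait model
#'
#' Multivariate normal log-density `-(n/2) log 2 pi - (1/2) log|V|
#' - (1/2) (y - W theta)' V^-1 (y - W theta)` with the regime weight matrix W
#' and covariance V implied by the model; BM models use a constant mean
#' vector `mu * 1`.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param regimes a `regime_map`.
#' @param tip_values named numeric vector of tip trait values.
#' @param model one of `BM1, BMS, OU1, OUM, OUMV, OUMA, OUMVA`.
#' @param params list with entries as required by the model: `theta`
#'   (per-regime for theta-varying models, scalar otherwise; for BM models
#'   `mu` may be used instead), `alpha`, `sigma2` (per-regime or scalar).
#' @param root_mode `"fixed"` or `"stationary"`.
#' @return the log-likelihood (scalar).
#' @export
ou_loglik <- function(tree, regimes, tip_values, model, params,
                      root_mode = "fixed") {
  pre <- ou_precompute(tree, regimes)
  spec <- model_spec_row(model, pre$n_regimes)
  y <- align_tip_values(tip_values, pre$tip_labels)
  theta <- params$theta
  if (is.null(theta)) theta <- params$mu
  if (is.null(theta)) stop("params must include `theta` (or `mu`)", call. = FALSE)
  alpha <- if (spec$is_ou) {
    resolve_regime_param(params$alpha, pre$levels, "alpha")
  } else rep(0, pre$n_regimes)
  sigma2 <- resolve_regime_param(params$sigma2, pre$levels, "sigma2")
  if (any(sigma2 <= 0)) stop("sigma^2 must be > 0", call. = FALSE)
  if (spec$is_ou && any(alpha < 0)) stop("alpha must be >= 0", call. = FALSE)

  mom <- ou_moments(pre, alpha, sigma2, root_mode)
  if (spec$theta_by_regime) {
    theta <- resolve_regime_param(theta, pre$levels, "theta")
    mean_vec <- mom$W %*% theta
  } else {
    mean_vec <- rep(as.numeric(theta)[1], pre$ntip)
  }
  L <- tryCatch(chol(mom$V), error = function(e) {
    stop("covariance is singular or not positive definite", call. = FALSE)
  })
  r <- backsolve(L, y - mean_vec, transpose = TRUE)
  as.numeric(-0.5 * pre$ntip * log(2 * pi) - sum(log(diag(L))) -
               0.5 * sum(r^2))
}

align_tip_values <- function(tip_values, tip_labels) {
  if (is.null(names(tip_values))) {
    if (length(tip_values) != length(tip_labels)) {
      stop("`tip_values` must be named by tip label", call. = FALSE)
    }
    return(as.numeric(tip_values))
  }
  miss <- setdiff(tip_labels, names(tip_values))
  if (length(miss) > 0) {
    stop("tips without a value: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  as.numeric(tip_values[tip_labels])
}

#' Fitting configuration for the trait-model engine
#'
#' @param n_alpha_starts,n_sigma_starts size of the deterministic start grid
#'   (alpha log-spaced over `alpha_bounds`, sigma^2 multipliers around a
#'   Brownian-rate data scaling).
#' @param n_polish number of best grid points polished by bounded
#'   quasi-Newton (L-BFGS-B on log parameters).
#' @param alpha_bounds bounds for alpha in units of 1/tree-depth
#'   (default `c(1e-4, 50)`).
#' @param root_mode `"fixed"` (default) or `"stationary"`.
#' @param criterion `"AICc"` (default) or `"AIC"` for model ranking.
#' @param factr L-BFGS-B convergence control (see [stats::optim()]).
#' @return list of class `ou_fit_config`.
#' @export
ou_fit_config <- function(n_alpha_starts = 5, n_sigma_starts = 5,
                          n_polish = 2, alpha_bounds = c(1e-4, 50),
                          root_mode = c("fixed", "stationary"),
                          criterion = c("AICc", "AIC"), factr = 1e7) {
  structure(list(n_alpha_starts = n_alpha_starts,
                 n_sigma_starts = n_sigma_starts,
                 n_polish = n_polish, alpha_bounds = alpha_bounds,
                 root_mode = match.arg(root_mode),
                 criterion = match.arg(criterion), factr = factr),
            class = "ou_fit_config")
}

#' Maximum-likelihood fit of one trait-evolution model
#'
#' theta (and the BM root mean) are profiled out by GLS at every evaluation;
#' the remaining (alpha, sigma^2) parameters are optimized on the log scale
#' by L-BFGS-B from a deterministic multi-start grid (all restart objectives
#' are retained in the result). Standard errors for theta come from the
#' numerically inverted Hessian of the full likelihood at the optimum.
#'
#' @inheritParams ou_loglik
#' @param config an [ou_fit_config()].
#' @param start optional list with `alpha` and/or `sigma2` (per-regime or
#'   scalar) used as an additional start (e.g. bootstrap refits from the
#'   generating MLEs).
#' @param se compute standard errors for theta from the numeric Hessian
#'   (skipped by the model-comparison and bootstrap loops, which do not use
#'   them).
#' @param warn_bound emit a warning when an alpha estimate sits at the upper
#'   search bound; the comparison and bootstrap loops record the
#'   `alpha_at_bound` flag instead of warning repeatedly.
#' @return an `ou_fit` object: list with the model name, per-regime
#'   estimates `theta`, `alpha`, `sigma2`, `loglik`, `k`, `AIC`, `AICc`,
#'   `theta_se`, `restarts` (grid/polish diagnostics), `convergence` and
#'   `alpha_at_bound`.
#' @export
fit_ou_model <- function(tree, regimes, tip_values, model,
                         config = ou_fit_config(), start = NULL, se = TRUE,
                         warn_bound = TRUE) {
  pre <- ou_precompute(tree, regimes)
  spec <- model_spec_row(model, pre$n_regimes)
  y <- align_tip_values(tip_values, pre$tip_labels)
  n <- pre$ntip
  if (n < spec$k + 2) {
    stop(sprintf("model %s needs at least k + 2 = %d tips (have %d)",
                 model, spec$k + 2, n), call. = FALSE)
  }
  ult <- check_ultrametric(pre$tree, rel_tol = 1e-4)
  if (spec$is_ou && !ult$ultrametric) {
    stop("OU models require an ultrametric tree (relative depth spread ",
         signif(ult$max_deviation, 3), ")", call. = FALSE)
  }

  T_depth <- pre$depth
  a_lo <- config$alpha_bounds[1] / T_depth
  a_hi <- config$alpha_bounds[2] / T_depth
  s0 <- brownian_rate_scale(pre, y)
  vy <- stats::var(y)

  # deterministic start grid
  a_starts <- if (spec$is_ou) {
    exp(seq(log(a_lo * 10), log(a_hi / 2), length.out = config$n_alpha_starts))
  } else 0
  s_mults <- exp(seq(log(0.1), log(10), length.out = config$n_sigma_starts))
  starts <- list()
  for (a0 in a_starts) {
    s_scale <- max(s0, 2 * a0 * vy)
    for (m in s_mults) starts[[length(starts) + 1]] <- c(a0, m * s_scale)
  }
  phi_of <- function(a0, sg0) {
    c(if (spec$is_ou) rep(log(a0), if (spec$alpha_by_regime) pre$n_regimes else 1),
      rep(log(sg0), if (spec$sigma_by_regime) pre$n_regimes else 1))
  }
  phis <- lapply(starts, function(st) phi_of(max(st[1], a_lo), st[2]))
  if (!is.null(start)) {
    a0 <- if (spec$is_ou) {
      resolve_regime_param(start$alpha, pre$levels, "alpha")
    } else rep(0, pre$n_regimes)
    s0v <- resolve_regime_param(start$sigma2, pre$levels, "sigma2")
    phi_extra <- c(
      if (spec$is_ou) {
        av <- pmin(pmax(a0, a_lo), a_hi)
        if (spec$alpha_by_regime) log(av) else log(av[1])
      },
      if (spec$sigma_by_regime) log(s0v) else log(s0v[1]))
    phis <- c(list(phi_extra), phis)
  }

  obj <- function(phi) {
    ll <- ou_profile_loglik(phi, pre, spec, y, config$root_mode)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  grid_obj <- vapply(phis, obj, numeric(1))
  ord <- order(grid_obj)
  n_polish <- min(config$n_polish, length(phis))
  lower <- c(if (spec$is_ou) rep(log(a_lo), if (spec$alpha_by_regime) pre$n_regimes else 1),
             rep(log(s0 * 1e-8), if (spec$sigma_by_regime) pre$n_regimes else 1))
  upper <- c(if (spec$is_ou) rep(log(a_hi), if (spec$alpha_by_regime) pre$n_regimes else 1),
             rep(log(max(s0, 2 * a_hi * vy) * 1e4),
                 if (spec$sigma_by_regime) pre$n_regimes else 1))

  polished <- list()
  for (idx in ord[seq_len(n_polish)]) {
    phi0 <- pmin(pmax(phis[[idx]], lower), upper)
    opt <- try(stats::optim(phi0, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = config$factr, maxit = 100)),
               silent = TRUE)
    if (!inherits(opt, "try-error")) {
      polished[[length(polished) + 1]] <- list(start = idx, opt = opt)
    }
  }
  if (length(polished) == 0) {
    stop("all optimization restarts failed for model ", model, call. = FALSE)
  }
  objs <- vapply(polished, function(p) p$opt$value, numeric(1))
  best <- polished[[which.min(objs)]]
  phi_hat <- best$opt$par
  sol <- ou_profile_loglik(phi_hat, pre, spec, y, config$root_mode)
  if (!is.finite(sol$loglik)) {
    stop("optimum is not finite for model ", model, call. = FALSE)
  }

  k <- spec$k
  aic <- 2 * k - 2 * sol$loglik
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  theta <- if (spec$theta_by_regime) {
    stats::setNames(sol$theta, pre$levels)
  } else stats::setNames(sol$theta, if (spec$is_ou) "theta" else "mu")

  restarts <- data.frame(
    start = seq_along(phis),
    objective = grid_obj,
    polished = vapply(seq_along(phis), function(i) {
      hit <- vapply(polished, function(p) p$start == i, logical(1))
      if (any(hit)) polished[[which(hit)[1]]]$opt$value else NA_real_
    }, numeric(1)))

  alpha_hat <- if (spec$is_ou) stats::setNames(sol$alpha, pre$levels) else NULL
  at_bound <- spec$is_ou && any(sol$alpha > 0.99 * a_hi)
  if (at_bound && warn_bound) {
    warning("alpha estimate at the upper search bound for model ", model,
            call. = FALSE)
  }

  fit <- structure(list(
    model = model, levels = pre$levels,
    theta = theta,
    alpha = alpha_hat,
    sigma2 = stats::setNames(sol$sigma2, pre$levels),
    root_mode = config$root_mode,
    loglik = sol$loglik, k = k, n = n,
    AIC = aic, AICc = aicc,
    theta_se = NULL,
    restarts = restarts,
    convergence = best$opt$convergence,
    alpha_at_bound = at_bound,
    phi_hat = phi_hat, spec = spec), class = "ou_fit")
  if (se) fit$theta_se <- theta_standard_errors(fit, pre, y, config$root_mode)
  fit
}

# Numeric Hessian of the full negative log-likelihood in (theta, phi) at the
# optimum; returns per-theta standard errors (NA on failure).
theta_standard_errors <- function(fit, pre, y, root_mode) {
  spec <- fit$spec
  nt <- length(fit$theta)
  est <- which(!is.na(fit$theta))
  full_nll <- function(par) {
    theta <- rep(0, nt)
    theta[est] <- par[seq_along(est)]
    phi <- par[-seq_along(est)]
    sol <- ou_profile_loglik(phi, pre, spec, y, root_mode)
    if (!is.finite(sol$loglik)) return(1e10)
    resid_mean <- if (spec$theta_by_regime) sol$W %*% theta else
      rep(theta[1], pre$ntip)
    L <- try(chol(sol$V), silent = TRUE)
    if (inherits(L, "try-error")) return(1e10)
    r <- backsolve(L, y - resid_mean, transpose = TRUE)
    0.5 * pre$ntip * log(2 * pi) + sum(log(diag(L))) + 0.5 * sum(r^2)
  }
  par0 <- c(as.numeric(fit$theta[est]), fit$phi_hat)
  H <- try(stats::optimHess(par0, full_nll), silent = TRUE)
  se <- rep(NA_real_, nt)
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error")) {
      d <- diag(Vi)[seq_along(est)]
      ok <- d > 0
      se[est[ok]] <- sqrt(d[ok])
    }
  }
  stats::setNames(se, names(fit$theta))
}

# Data-scaled Brownian rate used to seed and bound the sigma^2 search:
# GLS REML rate of y on the unit-rate Brownian covariance.
brownian_rate_scale <- function(pre, y) {
  mom <- ou_moments(pre, rep(0, pre$n_regimes), rep(1, pre$n_regimes), "fixed")
  L <- chol(mom$V)
  Liy <- backsolve(L, y, transpose = TRUE)
  Li1 <- backsolve(L, rep(1, pre$ntip), transpose = TRUE)
  mu <- sum(Li1 * Liy) / sum(Li1^2)
  max(sum((Liy - mu * Li1)^2) / (pre$ntip - 1), .Machine$double.eps)
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s root): logL = %.4f, k = %d, AICc = %.4f\n",
              x$model, x$root_mode, x$loglik, x$k, x$AICc))
  cat("  theta :", paste(sprintf("%s = %.6g", names(x$theta), x$theta),
                         collapse = ", "), "\n")
  if (!is.null(x$alpha)) {
    cat("  alpha :", paste(sprintf("%s = %.6g", names(x$alpha), x$alpha),
                           collapse = ", "), "\n")
  }
  cat("  sigma2:", paste(sprintf("%s = %.6g", names(x$sigma2), x$sigma2),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Fit and rank the seven-trait-model suite by Akaike weights
#'
#' Fits BM1, BMS, OU1, OUM, OUMV, OUMA and OUMVA, ranks them on the
#' configured criterion (AICc by default), converts differences to Akaike
#' weights `w = exp(-delta/2) / sum(exp(-delta/2))`, and marks the selected
#' set: the best model plus every model whose evidence ratio
#' `w_best / w_m` is below 3. Ties in the criterion are broken toward the
#' smaller parameter count, then fixed model order. Models whose AICc is
#' undefined (`n <= k + 1`) are excluded with a recorded reason.
#'
#' @inheritParams fit_ou_model
#' @param evidence_threshold evidence-ratio cut for the selected set
#'   (default 3).
#' @return a `model_comparison`: list with `table` (model, logL, k, AIC,
#'   AICc, delta, AICw, evidence_ratio, selected), `fits` (named list of
#'   `ou_fit`), `best` (best model name), `excluded` (named reasons).
#' @export
compare_models <- function(tree, regimes, tip_values,
                           config = ou_fit_config(),
                           evidence_threshold = 3) {
  specs <- ou_model_specs(length(regimes$levels))
  n <- ape::Ntip(tree)
  fits <- list()
  excluded <- character(0)
  for (m in specs$model) {
    k <- specs$k[specs$model == m]
    if (config$criterion == "AICc" && n - k - 1 <= 0) {
      excluded[[m]] <- sprintf("AICc undefined: n = %d <= k + 1 = %d", n, k + 1)
      next
    }
    if (n < k + 2) {
      excluded[[m]] <- sprintf("too few tips: n = %d < k + 2 = %d", n, k + 2)
      next
    }
    fits[[m]] <- fit_ou_model(tree, regimes, tip_values, m, config,
                              se = FALSE, warn_bound = FALSE)
  }
  if (length(fits) == 0) stop("no model could be fitted", call. = FALSE)

  crit <- vapply(fits, function(f) {
    if (config$criterion == "AICc") f$AICc else f$AIC
  }, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  model_order <- match(names(fits), specs$model)
  rank_order <- order(crit, ks, model_order)
  delta <- crit - min(crit)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  best <- names(fits)[rank_order[1]]
  er <- w[[best]] / w
  selected <- names(fits) == best | er < evidence_threshold

  tab <- data.frame(
    model = names(fits),
    logL = vapply(fits, function(f) f$loglik, numeric(1)),
    k = ks,
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    delta = delta, AICw = as.numeric(w), evidence_ratio = as.numeric(er),
    selected = selected,
    alpha_at_bound = vapply(fits, function(f) isTRUE(f$alpha_at_bound),
                            logical(1)),
    stringsAsFactors = FALSE)
  tab <- tab[rank_order, , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(table = tab, fits = fits, best = best,
                 criterion = config$criterion, excluded = excluded),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (", x$criterion, "):\n", sep = "")
  print(x$table, digits = 5)
  if (length(x$excluded) > 0) {
    cat("excluded:", paste(names(x$excluded), x$excluded, sep = ": ",
                           collapse = "; "), "\n")
  }
  invisible(x)
}

#' Akaike weights and evidence ratios from information-criterion values
#'
#' @param values numeric vector of AIC/AICc values (optionally named).
#' @param evidence_threshold evidence-ratio cut for the selected set.
#' @return data.frame with `delta`, `weight`, `evidence_ratio`, `selected`.
#' @examples
#' akaike_weights(c(10, 12, 14))
#' @export
akaike_weights <- function(values, evidence_threshold = 3) {
  delta <- values - min(values)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  er <- max(w) / w
  data.frame(delta = delta, weight = w, evidence_ratio = er,
             selected = er < evidence_threshold | w == max(w))
}
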