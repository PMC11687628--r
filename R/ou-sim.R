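#' Simulate tip values under a trait-evolution model
#'
#' Draws one realization `y ~ MVN(W theta, V)` (BM models: mean `mu * 1`)
#' via the Cholesky factor of the model covariance. Identical
#' `(seed, inputs)` give identical output.
#'
#' @inheritParams ou_loglik
#' @param seed integer seed; the draw is made inside
#'   [withr::with_seed()] so the caller's RNG state is untouched.
#' @return named numeric vector of tip values (tree tip order).
#' @export
simulate_tips <- function(tree, regimes, model, params, seed,
                          root_mode = "fixed") {
  pre <- ou_precompute(tree, regimes)
  spec <- model_spec_row(model, pre$n_regimes)
  if (!spec$is_ou) root_mode <- "fixed"
  alpha <- if (spec$is_ou) {
    resolve_regime_param(params$alpha, pre$levels, "alpha")
  } else rep(0, pre$n_regimes)
  sigma2 <- resolve_regime_param(params$sigma2, pre$levels, "sigma2")
  if (any(sigma2 <= 0)) stop("sigma^2 must be > 0", call. = FALSE)
  if (any(alpha < 0)) stop("alpha must be >= 0", call. = FALSE)
  theta <- params$theta
  if (is.null(theta)) theta <- params$mu
  if (is.null(theta)) stop("params must include `theta` (or `mu`)", call. = FALSE)

  mom <- ou_moments(pre, alpha, sigma2, root_mode)
  mean_vec <- if (spec$theta_by_regime) {
    as.vector(mom$W %*% resolve_regime_param(theta, pre$levels, "theta"))
  } else rep(as.numeric(theta)[1], pre$ntip)
  L <- tryCatch(chol(mom$V), error = function(e) {
    stop("covariance is singular or not positive definite", call. = FALSE)
  })
  z <- withr::with_seed(seed, stats::rnorm(pre$ntip))
  stats::setNames(mean_vec + as.vector(crossprod(L, z)), pre$tip_labels)
}
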