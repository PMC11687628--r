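#' Phylogenetic generalized least squares regression on a regime predictor
#'
#' GLS fit of a clade-level response on the meiosis-regime indicator
#' (symmetric = 0, asymmetric = 1) with residual covariance proportional to
#' shared branch lengths on the clade tree (Pagel's lambda scaling of the
#' off-diagonal elements; lambda = 1 is the Brownian default, lambda = 0 is
#' OLS). The response is square-root transformed by default, the variance
#' stabilization used for frequencies and rate statistics.
#'
#' @param tree clade-level rooted `phylo`; tip labels must cover all clades.
#' @param response named numeric vector (per clade); must be >= 0 when
#'   `sqrt_transform` is TRUE.
#' @param predictor named vector: either regime labels
#'   (`asymmetric`/`symmetric`) or a numeric covariate.
#' @param lambda fixed Pagel's lambda in `[0, 1]`, ignored when
#'   `ml_lambda = TRUE`.
#' @param ml_lambda if TRUE, lambda is estimated by maximum likelihood on
#'   `[0, 1]`.
#' @param sqrt_transform apply `sqrt()` to the response (default TRUE).
#' @return a `pgls_fit` list: `coefficients` table (estimate, std error, t,
#'   two-sided P on n - 2 df), `lambda`, `ml_lambda`, `sqrt_transform`,
#'   `df_residual`, `sigma2`, `loglik`.
#' @export
pgls_fit <- function(tree, response, predictor, lambda = 1,
                     ml_lambda = FALSE, sqrt_transform = TRUE) {
  tips <- tree$tip.label
  y <- align_tip_values(response, tips)
  if (sqrt_transform) {
    if (any(y < 0)) {
      stop("negative response values: disable `sqrt_transform` or fix inputs",
           call. = FALSE)
    }
    y <- sqrt(y)
  }
  x <- if (is.null(names(predictor))) {
    if (length(predictor) != length(tips)) {
      stop("`predictor` must be named by clade or match the tip count",
           call. = FALSE)
    }
    predictor
  } else {
    miss <- setdiff(tips, names(predictor))
    if (length(miss) > 0) {
      stop("clades without a predictor value: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    predictor[tips]
  }
  if (!is.numeric(x)) {
    lv <- unique(as.character(x))
    known <- c("symmetric", "asymmetric")
    if (all(lv %in% known)) {
      x <- as.numeric(as.character(x) == "asymmetric")
    } else {
      if (length(lv) != 2) {
        stop("categorical predictor must have exactly 2 levels", call. = FALSE)
      }
      x <- as.numeric(as.character(x) == sort(lv)[1])
    }
  }
  X <- cbind(`(Intercept)` = 1, slope = as.numeric(x))
  if (qr(X)$rank < 2) stop("singular design matrix", call. = FALSE)

  C0 <- ape::vcv(tree)
  lambda_cov <- function(lam) {
    C <- lam * C0
    diag(C) <- diag(C0)
    C
  }
  gls_at <- function(lam) {
    C <- lambda_cov(lam)
    L <- chol(C)
    Ly <- backsolve(L, y, transpose = TRUE)
    LX <- backsolve(L, X, transpose = TRUE)
    beta <- solve(crossprod(LX), crossprod(LX, Ly))
    resid <- Ly - LX %*% beta
    n <- length(y)
    s2_ml <- sum(resid^2) / n
    ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2_ml) -
      sum(log(diag(L))) - 0.5 * n
    list(beta = beta, LX = LX, resid = resid, loglik = ll, L = L)
  }
  if (ml_lambda) {
    opt <- stats::optimize(function(l) -gls_at(l)$loglik,
                           interval = c(0, 1), tol = 1e-8)
    lambda <- opt$minimum
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  sol <- gls_at(lambda)
  n <- length(y)
  df <- n - 2
  s2 <- sum(sol$resid^2) / df
  vb <- s2 * solve(crossprod(sol$LX))
  se <- sqrt(diag(vb))
  tval <- as.numeric(sol$beta) / se
  pval <- 2 * stats::pt(-abs(tval), df)
  coef_tab <- data.frame(term = c("(Intercept)", "regime_asymmetric"),
                         estimate = as.numeric(sol$beta),
                         std_error = se, t_value = tval, p_value = pval,
                         stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, lambda = lambda,
                 ml_lambda = ml_lambda, sqrt_transform = sqrt_transform,
                 df_residual = df, sigma2 = s2, loglik = sol$loglik),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (lambda = %.3f%s, response %s): df = %d\n",
              x$lambda, if (x$ml_lambda) ", ML" else " fixed",
              if (x$sqrt_transform) "sqrt-transformed" else "raw",
              x$df_residual))
  print(x$coefficients, digits = 4)
  invisible(x)
}
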