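#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums (pairs where a > b, plus half the ties).
#' When `n1 * n2 <= 100` and there are no ties the two-sided P comes from
#' exact enumeration of the U distribution; otherwise the normal
#' approximation with continuity correction and the tie correction to the
#' variance is used.
#'
#' @param sample_a,sample_b numeric vectors (each nonempty).
#' @return a `mann_whitney` list: `U` (for sample_a), `p_value` (two-sided,
#'   capped at 1), `n1`, `n2`, `tie_correction` (logical), `method`.
#' @examples
#' mann_whitney(c(2, 3, 4), c(0.1, 0.2, 0.3))   # U = 9, complete separation
#' @export
mann_whitney <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a)
  sample_b <- as.numeric(sample_b)
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (!ties && n1 * n2 <= 100) {
    # exact: two-sided as twice the smaller tail (capped at 1)
    lo <- stats::pwilcox(U, n1, n2)
    hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (U == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(U = U, p_value = p, n1 = n1, n2 = n2,
                 tie_correction = ties, method = method),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g (n1 = %d, n2 = %d), two-sided P = %.4g [%s%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method,
              if (x$tie_correction) ", tie-corrected" else ""))
  invisible(x)
}
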