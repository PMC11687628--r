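#' Model specifications for the seven-trait-model suite
#'
#' Two Brownian motion models (BM1: one rate; BMS: one rate per regime) and
#' five Ornstein-Uhlenbeck models letting the optimum theta, the pull
#' strength alpha and the diffusion sigma^2 vary (or not) across painted
#' regimes. Parameter counts are for the default fixed-root mode, where OU
#' models tie the root state to the root regime's theta (no extra root
#' parameter) and BM models carry one root mean.
#'
#' @param n_regimes number of regimes on the tree (default 2).
#' @return data.frame with columns `model, is_ou, theta_by_regime,
#'   alpha_by_regime, sigma_by_regime, k`.
#' @export
ou_model_specs <- function(n_regimes = 2) {
  spec <- data.frame(
    model = c("BM1", "BMS", "OU1", "OUM", "OUMV", "OUMA", "OUMVA"),
    is_ou = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    theta_by_regime = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    alpha_by_regime = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    sigma_by_regime = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  r <- n_regimes
  spec$k <- ifelse(spec$theta_by_regime, r, 1) +
    ifelse(spec$is_ou, ifelse(spec$alpha_by_regime, r, 1), 0) +
    ifelse(spec$sigma_by_regime, r, 1)
  spec
}

model_spec_row <- function(model, n_regimes = 2) {
  specs <- ou_model_specs(n_regimes)
  row <- specs[specs$model == model, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("unknown model '", model, "'; choose one of ",
         paste(specs$model, collapse = ", "), call. = FALSE)
  }
  row
}

# One-off structural precomputation shared by every likelihood evaluation on
# a given (tree, painting): preorder edge arrays, node-by-edge path
# membership, and the pairwise-MRCA index matrix.
ou_precompute <- function(tree, regimes) {
  stopifnot(inherits(tree, "phylo"), inherits(regimes, "regime_map"))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  nedge <- nrow(tree$edge)
  levels <- regimes$levels
  edge_reg <- match(regimes$edge_regime, levels)
  if (anyNA(edge_reg) || length(edge_reg) != nedge) {
    stop("regime map does not match the tree's edges", call. = FALSE)
  }

  # path membership: path_mat[v, e] = 1 iff edge e lies on root -> v
  path_mat <- matrix(0, nnode, nedge)
  for (e in seq_len(nedge)) {
    p <- tree$edge[e, 1]
    v <- tree$edge[e, 2]
    path_mat[v, ] <- path_mat[p, ]
    path_mat[v, e] <- 1
  }

  mrca_full <- ape::mrca(tree, full = FALSE)   # ntip x ntip, diagonal = tip
  depths <- node_depths(tree)

  # per-regime tip-path membership, so W needs one matmul per regime
  tip_path <- path_mat[seq_len(ntip), , drop = FALSE]
  tip_path_reg <- lapply(seq_along(levels), function(r) {
    m <- tip_path
    m[, edge_reg != r] <- 0
    m
  })

  list(tree = tree, ntip = ntip, nnode = nnode, nedge = nedge,
       parent = tree$edge[, 1], child = tree$edge[, 2],
       len = tree$edge.length, edge_reg = edge_reg,
       levels = levels, n_regimes = length(levels),
       root_reg = match(regimes$root_regime, levels),
       path_mat = path_mat, tip_path = tip_path,
       tip_path_reg = tip_path_reg,
       mrca = as.vector(mrca_full), depth = max(depths[seq_len(ntip)]),
       tip_labels = tree$tip.label)
}

# Core moment computation for one parameter point. `alpha_r`, `sigma2_r` are
# per-regime vectors (alpha all zero for BM). Returns tip expectation weights
# W (tips x regimes), covariance V (tips x tips), and per-node attenuations.
ou_moments <- function(pre, alpha_r, sigma2_r, root_mode = "fixed") {
  a_e <- alpha_r[pre$edge_reg]
  s2_e <- sigma2_r[pre$edge_reg]
  len <- pre$len
  any_pull <- any(alpha_r > 0)

  # cumulative attenuation e^{-A(root -> node)}
  if (any_pull) {
    E <- exp(-as.vector(pre$path_mat %*% (a_e * len)))
  } else {
    E <- rep(1, pre$nnode)
  }
  E_child <- E[pre$child]

  # per-edge variance input (sigma^2/2a)(1 - e^{-2 a l}), -> sigma^2 l as a->0
  if (any_pull) {
    a_pos <- pmax(a_e, .Machine$double.xmin)
    s_e <- s2_e * (1 - exp(-2 * a_e * len)) / (2 * a_pos)
    s_e[a_e == 0] <- (s2_e * len)[a_e == 0]
  } else {
    s_e <- s2_e * len
  }
  q <- E^2 * as.vector(pre$path_mat %*% (s_e / E_child^2))
  if (root_mode == "stationary") {
    a_root <- alpha_r[pre$root_reg]
    if (a_root <= 0) {
      stop("stationary root mode requires alpha > 0 in the root regime",
           call. = FALSE)
    }
    q <- q + (sigma2_r[pre$root_reg] / (2 * a_root)) * E^2
  }

  E_tip <- E[seq_len(pre$ntip)]
  em <- E[pre$mrca]
  V <- (q[pre$mrca] / (em * em)) * tcrossprod(E_tip)
  dim(V) <- c(pre$ntip, pre$ntip)

  # regime weights for the tip expectations
  W <- matrix(0, pre$ntip, pre$n_regimes)
  if (any_pull) {
    g_e <- (1 - exp(-a_e * len)) / E_child
    for (r in seq_len(pre$n_regimes)) {
      W[, r] <- E_tip * as.vector(pre$tip_path_reg[[r]] %*% g_e)
    }
  }
  W[, pre$root_reg] <- W[, pre$root_reg] + E_tip
  list(W = W, V = V, E_tip = E_tip)
}

#' Regime weight matrix for tip expectations under a multi-regime OU model
#'
#' Row i gives, for each regime, the share of tip i's expected value
#' attributable to that regime's optimum theta, from the piecewise-constant
#' pull alpha along the root-to-tip path. The residual weight of the
#' (attenuated) root state goes to the root regime's column, so each row
#' sums to 1.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param regimes a `regime_map` from [paint_regimes()].
#' @param alphas named per-regime vector of pull strengths (>= 0; 0 is the
#'   Brownian limit).
#' @param root_mode `"fixed"` (default) or `"stationary"`; the weight matrix
#'   is the same in both, the option is accepted for interface symmetry.
#' @return tips x regimes matrix with rows summing to 1; regime order follows
#'   `regimes$levels`, row order the tree's tip order.
#' @export
build_design <- function(tree, regimes, alphas, root_mode = "fixed") {
  pre <- ou_precompute(tree, regimes)
  alphas <- resolve_regime_param(alphas, pre$levels, "alphas")
  if (any(alphas < 0)) stop("alpha must be >= 0", call. = FALSE)
  mom <- ou_moments(pre, alphas, rep(1, pre$n_regimes), root_mode = "fixed")
  dimnames(mom$W) <- list(pre$tip_labels, pre$levels)
  mom$W
}

#' Tip covariance matrix under a multi-regime OU (or BM) model
#'
#' Entry (i, j) accumulates diffusion along the shared root-to-MRCA path,
#' each branch segment contributing `(sigma^2/2 alpha)(1 - e^{-2 alpha l})`
#' attenuated by the pull acting on the remaining shared path, and is then
#' attenuated down both private paths. With all alpha = 0 this reduces to
#' the Brownian `sum(sigma^2 l)` over the shared path. The default root is
#' fixed (zero root variance); `root_mode = "stationary"` adds the root
#' regime's stationary variance `sigma^2 / (2 alpha)`.
#'
#' @inheritParams build_design
#' @param sigmas named per-regime vector of diffusion rates sigma^2 (> 0).
#' @return symmetric positive-definite tips x tips matrix.
#' @export
build_covariance <- function(tree, regimes, alphas, sigmas,
                             root_mode = "fixed") {
  pre <- ou_precompute(tree, regimes)
  alphas <- resolve_regime_param(alphas, pre$levels, "alphas")
  sigmas <- resolve_regime_param(sigmas, pre$levels, "sigmas")
  if (any(alphas < 0)) stop("alpha must be >= 0", call. = FALSE)
  if (any(sigmas <= 0)) stop("sigma^2 must be > 0", call. = FALSE)
  V <- ou_moments(pre, alphas, sigmas, root_mode = root_mode)$V
  ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    stop(sprintf("covariance is not positive definite (smallest eigenvalue %g)",
                 ev), call. = FALSE)
  }
  dimnames(V) <- list(pre$tip_labels, pre$tip_labels)
  V
}

# Accept either a scalar (recycled), an unnamed vector in level order, or a
# vector named by regime level.
resolve_regime_param <- function(x, levels, what) {
  r <- length(levels)
  if (length(x) == 1 && is.null(names(x))) return(rep(as.numeric(x), r))
  if (!is.null(names(x))) {
    miss <- setdiff(levels, names(x))
    if (length(miss) > 0) {
      stop("`", what, "` missing regime(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(as.numeric(x[levels]))
  }
  if (length(x) != r) {
    stop("`", what, "` must have one value per regime", call. = FALSE)
  }
  as.numeric(x)
}
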