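# Independent numerical oracles used across the test suite.
# These deliberately avoid the package's own moment algebra: moments are
# obtained by Runge-Kutta integration of the piecewise OU moment ODEs
# (m' = alpha (theta - m); v' = -2 alpha v + sigma^2; covariances of
# diverged lineages decay at rate alpha_i + alpha_j with no shared noise).

# Joint tip moments (mean vector, covariance matrix) by RK4 through the
# tree's epochs. theta_r / alpha_r / sigma2_r are per-regime vectors in
# regimes$levels order. Fixed root at theta of the root regime (x0 may
# override), zero root variance unless root_var is given.
ode_tip_moments <- function(tree, regimes, theta_r, alpha_r, sigma2_r,
                            x0 = NULL, root_var = 0, steps_per_epoch = 120) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(tree)
  edge_reg <- match(regimes$edge_regime, regimes$levels)
  if (is.null(x0)) x0 <- theta_r[match(regimes$root_regime, regimes$levels)]

  # event times: node depths where lineages split
  events <- sort(unique(round(depth[(ntip + 1):nnode], 12)))
  t_end <- max(depth[seq_len(ntip)])
  boundaries <- sort(unique(c(events, t_end)))

  # active lineages = edges; start with root's child edges
  kids <- function(node) which(tree$edge[, 1] == node)
  active <- kids(root)
  m <- rep(x0, length(active))
  V <- matrix(root_var, length(active), length(active))
  diag(V) <- root_var
  t_now <- 0

  for (tb in boundaries[boundaries > 1e-15]) {
    # integrate from t_now to tb
    h <- (tb - t_now) / steps_per_epoch
    a <- alpha_r[edge_reg[active]]
    th <- theta_r[edge_reg[active]]
    s2 <- sigma2_r[edge_reg[active]]
    A <- outer(a, a, "+")
    D <- diag(s2, length(active))
    for (s in seq_len(steps_per_epoch)) {
      f_m <- function(mm) a * (th - mm)
      f_V <- function(VV) -A * VV + D
      k1m <- f_m(m);              k1V <- f_V(V)
      k2m <- f_m(m + h / 2 * k1m); k2V <- f_V(V + h / 2 * k1V)
      k3m <- f_m(m + h / 2 * k2m); k3V <- f_V(V + h / 2 * k2V)
      k4m <- f_m(m + h * k3m);     k4V <- f_V(V + h * k3V)
      m <- m + h / 6 * (k1m + 2 * k2m + 2 * k3m + k4m)
      V <- V + h / 6 * (k1V + 2 * k2V + 2 * k3V + k4V)
    }
    t_now <- tb
    # split lineages whose child node is an internal node at depth tb
    repeat {
      ends <- tree$edge[active, 2]
      split_idx <- which(ends > ntip & abs(depth[ends] - tb) < 1e-12)
      if (length(split_idx) == 0) break
      i <- split_idx[1]
      node <- tree$edge[active[i], 2]
      ch <- kids(node)
      # duplicate row/col i into the new lineages
      keep <- seq_along(active)[-i]
      new_active <- c(active[keep], ch)
      idx <- c(keep, i, i)
      V <- V[idx, idx, drop = FALSE]
      m <- m[idx]
      active <- new_active
    }
  }
  tip_of <- tree$edge[active, 2]
  ord <- order(tip_of)
  list(mean = m[ord], cov = V[ord, ord, drop = FALSE],
       tips = tree$tip.label[tip_of[ord]])
}

# GLS estimates under unit-rate Brownian covariance: generalized mean and
# REML rate, from the full phylogenetic covariance matrix.
gls_brownian <- function(tree, y) {
  C <- ape::vcv(tree)
  y <- y[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, length(y))
  mu <- as.numeric((t(one) %*% Ci %*% y) / (t(one) %*% Ci %*% one))
  n <- length(y)
  rate_reml <- as.numeric(t(y - mu) %*% Ci %*% (y - mu)) / (n - 1)
  list(mu = mu, rate_reml = rate_reml)
}

# Brute-force minimal-change count for a binary-state painting: enumerate
# all internal-node labelings and count parent/child mismatches.
fitch_min_changes <- function(tree, tip_states, levels) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  states <- match(tip_states[tree$tip.label], levels)
  best <- Inf
  for (code in 0:(2^nint - 1)) {
    lab <- c(states, as.integer(intToBits(code))[seq_len(nint)] + 1L)
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# random ultrametric tree with a random 2-regime painting (seeded)
random_painted_tree <- function(n_tips, seed, depth = 1) {
  tr <- yule_tree(n_tips, seed = seed, depth = depth)
  tips <- withr::with_seed(seed + 1000L, {
    k <- sample(1:(n_tips - 1), 1)
    sample(tr$tip.label, k)
  })
  regs <- stats::setNames(
    ifelse(tr$tip.label %in% tips, "asymmetric", "symmetric"),
    tr$tip.label)
  root_reg <- if (withr::with_seed(seed + 2000L, stats::runif(1)) < 0.5) {
    "asymmetric"
  } else "symmetric"
  list(tree = tr,
       regimes = paint_regimes(tr, regs, root_regime = root_reg,
                               levels = c("asymmetric", "symmetric")))
}

# study-like clustered regime painting: the symmetric regime occupies the
# subtree whose tip count is closest to the requested fraction
clustered_regimes <- function(tree, frac = 6 / 27) {
  n <- ape::Ntip(tree)
  best <- NULL
  best_d <- Inf
  for (node in (n + 2):(n + tree$Nnode)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    d <- abs(length(tips) - frac * n)
    if (d < best_d && length(tips) >= 2 && length(tips) <= n / 2) {
      best_d <- d
      best <- tips
    }
  }
  stats::setNames(ifelse(tree$tip.label %in% best, "symmetric", "asymmetric"),
                  tree$tip.label)
}
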