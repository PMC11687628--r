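lv <- c("asymmetric", "symmetric")

test_that("model specifications carry the documented parameter counts", {
  specs <- ou_model_specs(2)
  expect_equal(setNames(specs$k, specs$model),
               c(BM1 = 2, BMS = 3, OU1 = 3, OUM = 4, OUMV = 5, OUMA = 5,
                 OUMVA = 6))
})

test_that("regime weight rows are stochastic and closed forms hold", {
  tr <- parse_newick("(A:1,B:1);")
  rmap <- paint_regimes(tr, c(A = "asymmetric", B = "symmetric"),
                        root_regime = "symmetric", levels = lv)
  W <- build_design(tr, rmap, alphas = c(asymmetric = 1, symmetric = 1))
  # tip A spends its whole depth-1 path in regime 1 with alpha = 1
  expect_equal(W["A", "asymmetric"], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(W["A", "symmetric"], exp(-1), tolerance = 1e-12)  # root share
  expect_equal(unname(rowSums(W)), c(1, 1), tolerance = 1e-12)

  for (s in 1:5) {
    rp <- random_painted_tree(8, seed = 600 + s)
    al <- withr::with_seed(s, setNames(runif(2, 0.1, 4), lv))
    Wr <- build_design(rp$tree, rp$regimes, al)
    expect_equal(unname(rowSums(Wr)), rep(1, 8), tolerance = 1e-12)
  }

  # single regime: all weight in one column regardless of alpha
  one <- paint_regimes(tr, c(A = "x", B = "x"), root_regime = "x")
  W1 <- build_design(tr, one, alphas = c(x = 3.3))
  expect_equal(unname(W1[, 1]), c(1, 1), tolerance = 1e-12)

  expect_error(build_design(tr, rmap, alphas = c(asymmetric = -1,
                                                 symmetric = 1)), ">= 0")
})

test_that("covariance matches closed forms and the Brownian limit", {
  star <- parse_newick("(A:1,B:1);")
  rmap <- paint_regimes(star, c(A = "x", B = "x"), root_regime = "x")
  V <- build_covariance(star, rmap, alphas = 1, sigmas = 2)
  expect_equal(V["A", "A"], (2 / 2) * (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(V["A", "B"], 0)

  tr <- yule_tree(10, seed = 21)
  reg <- paint_regimes(tr, setNames(rep("x", 10), tr$tip.label), "x")
  V_ou <- build_covariance(tr, reg, alphas = 1e-8, sigmas = 1.7)
  V_bm <- 1.7 * ape::vcv(tr)
  expect_lt(max(abs(V_ou - V_bm[rownames(V_ou), colnames(V_ou)]) /
                  max(V_bm)), 1e-6)

  expect_error(build_covariance(star, rmap, alphas = 1, sigmas = -2), "> 0")
})

test_that("moments match the numeric ODE oracle on painted trees", {
  for (s in 1:10) {
    rp <- random_painted_tree(4, seed = 700 + s)
    pars <- withr::with_seed(s, list(
      al = setNames(runif(2, 0.2, 3), lv),
      sg = setNames(runif(2, 0.3, 2), lv),
      th = setNames(rnorm(2, 0, 2), lv)))
    orc <- ode_tip_moments(rp$tree, rp$regimes, pars$th, pars$al, pars$sg)
    V <- build_covariance(rp$tree, rp$regimes, pars$al, pars$sg)
    W <- build_design(rp$tree, rp$regimes, pars$al)
    expect_lt(max(abs(V[orc$tips, orc$tips] - orc$cov)) / max(abs(orc$cov)),
              1e-6)
    mean_pkg <- (W %*% pars$th)[orc$tips, 1]
    expect_lt(max(abs(mean_pkg - orc$mean)), 1e-6)
  }
})

test_that("the likelihood reproduces closed forms and nesting", {
  star <- parse_newick("(A:1,B:1);")
  rmap <- paint_regimes(star, c(A = "x", B = "x"), root_regime = "x")
  ll <- ou_loglik(star, rmap, c(A = 0, B = 2), "BM1",
                  list(mu = 1, sigma2 = 1))
  expect_equal(ll, -log(2 * pi) - 1, tolerance = 1e-9)

  rp <- random_painted_tree(10, seed = 31)
  y <- simulate_tips(rp$tree, rp$regimes, "OUM",
                     list(theta = c(asymmetric = 1, symmetric = -1),
                          alpha = 2, sigma2 = 1), seed = 3)
  l_ou1 <- ou_loglik(rp$tree, rp$regimes, y, "OU1",
                     list(theta = 0.4, alpha = 2, sigma2 = 1))
  l_oum <- ou_loglik(rp$tree, rp$regimes, y, "OUM",
                     list(theta = c(asymmetric = 0.4, symmetric = 0.4),
                          alpha = 2, sigma2 = 1))
  expect_equal(l_ou1, l_oum, tolerance = 1e-10)

  # BM1 is the alpha -> 0 limit of OU1 (matched sigma^2 * t)
  l_bm <- ou_loglik(rp$tree, rp$regimes, y, "BM1", list(mu = 0.4, sigma2 = 1))
  l_ou_small <- ou_loglik(rp$tree, rp$regimes, y, "OU1",
                          list(theta = 0.4, alpha = 1e-8, sigma2 = 1))
  expect_lt(abs(l_bm - l_ou_small), 0.01)
})

test_that("profile likelihood at the optimum beats perturbed parameters", {
  rp <- random_painted_tree(40, seed = 91)
  y <- simulate_tips(rp$tree, rp$regimes, "OUM",
                     list(theta = c(asymmetric = 2, symmetric = 0),
                          alpha = 2, sigma2 = 0.7), seed = 8)
  fit <- fit_ou_model(rp$tree, rp$regimes, y, "OUM", se = FALSE)
  perturb <- withr::with_seed(10, replicate(100, {
    ou_loglik(rp$tree, rp$regimes, y, "OUM",
              list(theta = fit$theta + rnorm(2, 0, 0.2),
                   alpha = pmax(fit$alpha * exp(rnorm(1, 0, 0.3)), 1e-6),
                   sigma2 = fit$sigma2 * exp(rnorm(1, 0, 0.3))))
  }))
  expect_true(all(perturb <= fit$loglik + 1e-8))
})

test_that("BM1 maximum-likelihood rate matches the GLS closed form", {
  tr <- yule_tree(30, seed = 41)
  reg <- paint_regimes(tr, setNames(rep("x", 30), tr$tip.label), "x")
  y <- simulate_tips(tr, reg, "BM1", list(mu = 5, sigma2 = 2), seed = 17)
  fit <- fit_ou_model(tr, reg, y, "BM1", se = FALSE)
  C <- ape::vcv(tr)
  yv <- y[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, 30)
  mu <- as.numeric((one %*% Ci %*% yv) / (one %*% Ci %*% one))
  s2_ml <- as.numeric(t(yv - mu) %*% Ci %*% (yv - mu)) / 30
  expect_equal(unname(fit$sigma2[1]), s2_ml, tolerance = 1e-4)
  expect_equal(unname(fit$theta[1]), mu, tolerance = 1e-6)
})

test_that("model nesting is respected by the maximized likelihoods", {
  rp <- random_painted_tree(60, seed = 121)
  y <- simulate_tips(rp$tree, rp$regimes, "OUMV",
                     list(theta = c(asymmetric = 1.5, symmetric = 0),
                          alpha = 3,
                          sigma2 = c(asymmetric = 1.5, symmetric = 0.5)),
                     seed = 13)
  cfg <- ou_fit_config()
  fits <- suppressWarnings(
    lapply(setNames(nm = c("OU1", "OUM", "OUMV", "OUMA", "OUMVA")),
           function(m) fit_ou_model(rp$tree, rp$regimes, y, m, cfg,
                                    se = FALSE)))
  tol <- 1e-4
  expect_gte(fits$OUM$loglik, fits$OU1$loglik - tol)
  expect_gte(fits$OUMV$loglik, fits$OUM$loglik - tol)
  expect_gte(fits$OUMA$loglik, fits$OUM$loglik - tol)
  expect_gte(fits$OUMVA$loglik, fits$OUMV$loglik - tol)
  expect_gte(fits$OUMVA$loglik, fits$OUMA$loglik - tol)
})

test_that("a one-regime painting collapses OUM to the OU1 fit", {
  tr <- yule_tree(25, seed = 61)
  reg1 <- paint_regimes(tr, setNames(rep("asymmetric", 25), tr$tip.label),
                        root_regime = "asymmetric", levels = lv)
  y <- simulate_tips(tr, reg1, "OU1", list(theta = 1, alpha = 2, sigma2 = 1),
                     seed = 23)
  f_oum <- fit_ou_model(tr, reg1, y, "OUM", se = FALSE)
  f_ou1 <- fit_ou_model(tr, reg1, y, "OU1", se = FALSE)
  expect_equal(f_oum$loglik, f_ou1$loglik, tolerance = 1e-6)
})

test_that("stationary root mode adds the root regime's stationary variance", {
  tr <- parse_newick("(A:1,B:1);")
  rmap <- paint_regimes(tr, c(A = "x", B = "x"), root_regime = "x")
  V_fix <- build_covariance(tr, rmap, alphas = 1, sigmas = 2,
                            root_mode = "fixed")
  V_st <- build_covariance(tr, rmap, alphas = 1, sigmas = 2,
                           root_mode = "stationary")
  # diagonal becomes the full stationary variance sigma^2 / (2 alpha)
  expect_equal(unname(diag(V_st)), rep(1, 2), tolerance = 1e-12)
  expect_equal(unname(V_st["A", "B"]), exp(-2), tolerance = 1e-12)
  expect_true(all(V_st >= V_fix - 1e-15))

  rp <- random_painted_tree(20, seed = 141)
  y <- simulate_tips(rp$tree, rp$regimes, "OUM",
                     list(theta = c(asymmetric = 1, symmetric = 0),
                          alpha = 2, sigma2 = 1),
                     seed = 5, root_mode = "stationary")
  f <- fit_ou_model(rp$tree, rp$regimes, y, "OUM",
                    ou_fit_config(root_mode = "stationary"), se = FALSE)
  expect_true(is.finite(f$loglik))
  expect_equal(f$root_mode, "stationary")
})

test_that("Akaike weights, evidence ratios and the 3.0 rule", {
  w <- akaike_weights(c(10, 12, 14))
  expect_equal(w$weight, c(0.66524, 0.24473, 0.09003), tolerance = 1e-4)
  expect_equal(w$evidence_ratio, c(1, exp(1), exp(2)), tolerance = 1e-9)
  expect_equal(w$selected, c(TRUE, TRUE, FALSE))
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)

  weq <- akaike_weights(rep(3.3, 7))
  expect_equal(weq$weight, rep(1 / 7, 7), tolerance = 1e-12)
})

test_that("compare_models ranks the suite and weights sum to one", {
  rp <- random_painted_tree(50, seed = 151)
  y <- simulate_tips(rp$tree, rp$regimes, "OUM",
                     list(theta = c(asymmetric = 3, symmetric = -3),
                          alpha = 3, sigma2 = 0.5), seed = 29)
  cmp <- compare_models(rp$tree, rp$regimes, y)
  expect_equal(nrow(cmp$table), 7)
  expect_equal(sum(cmp$table$AICw), 1, tolerance = 1e-12)
  expect_equal(cmp$table$evidence_ratio[1], 1)
  expect_true(all(diff(cmp$table$AICc) >= 0))
  expect_true(cmp$best %in% c("OUM", "OUMV", "OUMA", "OUMVA"))
  expect_true(all(cmp$table$AICc >= cmp$table$AIC))

  # criterion switch changes ranking deltas, not likelihoods
  cmp_aic <- compare_models(rp$tree, rp$regimes, y,
                            config = ou_fit_config(criterion = "AIC"))
  expect_equal(sort(cmp_aic$table$logL), sort(cmp$table$logL),
               tolerance = 1e-5)

  # too-small trees exclude the big models with a recorded reason
  small <- random_painted_tree(6, seed = 161)
  ys <- simulate_tips(small$tree, small$regimes, "OU1",
                      list(theta = 0, alpha = 1, sigma2 = 1), seed = 31)
  cmp_s <- suppressWarnings(compare_models(small$tree, small$regimes, ys))
  expect_true("OUMVA" %in% names(cmp_s$excluded))
})

test_that("simulation is seed-deterministic with the model moments", {
  rp <- random_painted_tree(15, seed = 171)
  pars <- list(theta = c(asymmetric = 2, symmetric = -1), alpha = 2,
               sigma2 = 1)
  y1 <- simulate_tips(rp$tree, rp$regimes, "OUM", pars, seed = 99)
  y2 <- simulate_tips(rp$tree, rp$regimes, "OUM", pars, seed = 99)
  expect_identical(y1, y2)
  expect_false(identical(y1, simulate_tips(rp$tree, rp$regimes, "OUM", pars,
                                           seed = 100)))

  # sigma^2 -> 0: tips collapse onto the deterministic expectation W theta
  y0 <- simulate_tips(rp$tree, rp$regimes, "OUM",
                      modifyList(pars, list(sigma2 = 1e-12)), seed = 7)
  W <- build_design(rp$tree, rp$regimes, alphas = c(asymmetric = 2,
                                                    symmetric = 2))
  expect_equal(unname(y0), unname((W %*% pars$theta)[, 1]), tolerance = 1e-4)
})

test_that("simulated samples reproduce the analytic covariance", {
  rp <- random_painted_tree(4, seed = 181)
  pars <- list(theta = c(asymmetric = 0, symmetric = 0), alpha = 1.5,
               sigma2 = c(asymmetric = 2, symmetric = 0.6))
  V <- build_covariance(rp$tree, rp$regimes,
                        alphas = c(asymmetric = 1.5, symmetric = 1.5),
                        sigmas = pars$sigma2)
  n_rep <- 2000
  draws <- vapply(seq_len(n_rep), function(i) {
    simulate_tips(rp$tree, rp$regimes, "OUMV", pars, seed = 20000 + i)
  }, numeric(4))
  Vhat <- stats::cov(t(draws))
  # entrywise Monte-Carlo standard error of a sample covariance
  se_V <- sqrt((outer(diag(V), diag(V)) + V^2) / n_rep)
  expect_true(all(abs(Vhat - V) < 3.5 * se_V))
  expect_lt(max(abs(diag(Vhat) - diag(V)) / diag(V)), 0.1)
})

test_that("strong pull drives regime tip means to their optima", {
  tr <- yule_tree(200, seed = 191)
  regs <- withr::with_seed(192, setNames(sample(lv, 200, TRUE), tr$tip.label))
  rmap <- paint_regimes(tr, regs, root_regime = "asymmetric", levels = lv)
  a_hi <- 50   # alpha * depth = 50: essentially stationary at the tips
  pars <- list(theta = c(asymmetric = 4, symmetric = -4), alpha = a_hi,
               sigma2 = 1)
  hits <- vapply(1:30, function(i) {
    y <- simulate_tips(tr, rmap, "OUM", pars, seed = 40000 + i)
    m_a <- mean(y[regs == "asymmetric"])
    m_s <- mean(y[regs == "symmetric"])
    sd_st <- sqrt(1 / (2 * a_hi))
    abs(m_a - 4) < 3 * sd_st / sqrt(sum(regs == "asymmetric")) + 3 * sd_st &&
      abs(m_s + 4) < 3 * sd_st / sqrt(sum(regs == "symmetric")) + 3 * sd_st
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
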