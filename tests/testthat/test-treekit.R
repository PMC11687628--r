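test_that("parse_newick reads trees and preserves structure", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(2, 3))
  expect_true(check_ultrametric(tr)$ultrametric)
  expect_false(attr(tr, "polytomies"))

  poly <- parse_newick("((A:1,B:1,C:1):1,D:2);")
  expect_true(attr(poly, "polytomies"))

  single <- parse_newick("(A:1);")   # degenerate: no bifurcations
  expect_equal(ape::Ntip(single), 1)
  expect_equal(single$Nnode, 1)
})

test_that("parse_newick rejects malformed input with a character offset", {
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "character")
  expect_error(parse_newick("(A:1,B:1));"), "character 10")
  expect_error(parse_newick("((A:1,B):1,C:2);"), "branch length.*B")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicated")
})

test_that("newick round-trip preserves topology and branch lengths", {
  tr <- yule_tree(50, seed = 71, depth = 3)
  back <- parse_newick(write_newick(tr))
  d1 <- ape::cophenetic.phylo(tr)
  d2 <- ape::cophenetic.phylo(back)
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-9)
})

test_that("pruning preserves patristic distances and tip depths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  expect_equal(unname(ape::node.depth.edgelength(pr)[1:2]), c(2, 2))

  expect_identical(prune_to_taxa(tr, c("A", "B", "C")), tr)
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")

  big <- yule_tree(20, seed = 12)
  keep <- paste0("t", c(2, 5, 9, 13, 20))
  sub <- prune_to_taxa(big, keep)
  d_full <- ape::cophenetic.phylo(big)[keep, keep]
  d_sub <- ape::cophenetic.phylo(sub)[keep, keep]
  expect_lt(max(abs(d_full - d_sub)), 1e-9)
})

test_that("ultrametricity check flags unequal depths", {
  res <- check_ultrametric(parse_newick("((A:1,B:2):1,C:2);"), rel_tol = 1e-6)
  expect_false(res$ultrametric)
  expect_gt(res$max_deviation, 0.3)
  for (s in 1:5) {
    expect_true(check_ultrametric(yule_tree(10, seed = s),
                                  rel_tol = 1e-9)$ultrametric)
  }
})

test_that("polytomy resolution yields a binary tree usable for contrasts", {
  poly <- parse_newick("((A:1,B:1,C:1):1,D:2);")
  expect_error(independent_contrasts(poly, c(A = 1, B = 2, C = 3, D = 4)),
               "resolve")
  res <- resolve_polytomies(poly)
  expect_true(ape::is.binary(res))
  expect_true(all(res$edge.length > 0))
  pics <- independent_contrasts(res, c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(nrow(pics), 3)
})

test_that("Fitch painting matches hand and brute-force reconstructions", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  rmap <- paint_regimes(tr, c(A = "asymmetric", B = "asymmetric",
                              C = "symmetric"),
                        root_regime = "symmetric")
  # edges cladewise: root->(A,B) node, ->A, ->B, ->C
  expect_equal(rmap$edge_regime,
               c("asymmetric", "asymmetric", "asymmetric", "symmetric"))
  expect_equal(rmap$node_regime[4], "symmetric")  # root tie -> root_regime

  same <- paint_regimes(tr, c(A = "x", B = "x", C = "x"), root_regime = "x")
  expect_true(all(same$edge_regime == "x"))

  expect_error(paint_regimes(tr, c(A = "x", B = "x"), root_regime = "x"),
               "without a regime")

  # parsimony optimality vs exhaustive enumeration, incl. an alternating
  # caterpillar
  cat10 <- parse_newick(paste0(
    paste(rep("(", 9), collapse = ""),
    "A1:1,B1:1):1,A2:1):1,B2:1):1,A3:1):1,B3:1):1,A4:1):1,B4:1):1,A5:1):1,B5:1);"))
  states <- setNames(rep(c("asymmetric", "symmetric"), 5),
                     c(paste0("A", 1:5), paste0("B", 1:5)))
  lv <- c("asymmetric", "symmetric")
  pm <- paint_regimes(cat10, states, root_regime = "symmetric", levels = lv)
  expect_equal(karyodrive:::regime_changes(cat10, pm$node_regime),
               fitch_min_changes(cat10, states, lv))
  for (s in 1:8) {
    rt <- yule_tree(8, seed = 100 + s)
    st <- withr::with_seed(200 + s,
                           setNames(sample(lv, 8, replace = TRUE),
                                    rt$tip.label))
    if (length(unique(st)) == 1) next
    pm <- paint_regimes(rt, st, root_regime = lv[1], levels = lv)
    expect_equal(karyodrive:::regime_changes(rt, pm$node_regime),
                 fitch_min_changes(rt, st, lv))
  }
})

test_that("independent contrasts reproduce the pruning recursion", {
  two <- parse_newick("(A:1,B:1);")
  pic2 <- independent_contrasts(two, c(A = 3, B = 1))
  expect_equal(pic2$contrast, 2 / sqrt(2), tolerance = 1e-12)

  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pics <- independent_contrasts(tr, c(A = 2, B = 0, C = 4))
  expect_equal(sort(pics$contrast), sort(c(sqrt(2), (1 - 4) / sqrt(3.5))),
               tolerance = 1e-12)
  expect_equal(pics$node_value[pics$variance == 2], 1)
  expect_equal(pics$variance, c(2, 3.5))

  # cross-check against the reference implementation in ape
  for (s in 1:5) {
    rt <- yule_tree(12, seed = 300 + s)
    y <- withr::with_seed(s, setNames(rnorm(12), rt$tip.label))
    mine <- independent_contrasts(rt, y)
    ref <- ape::pic(y[rt$tip.label], rt)
    expect_equal(sort(abs(mine$contrast)), sort(abs(unname(ref))),
                 tolerance = 1e-10)
    expect_equal(nrow(mine), 11)
  }
})

test_that("contrasts agree with GLS under Brownian covariance", {
  for (s in 1:6) {
    n <- withr::with_seed(s, sample(4:8, 1))
    rt <- yule_tree(n, seed = 400 + s)
    y <- withr::with_seed(500 + s, setNames(rnorm(n, sd = 2), rt$tip.label))
    pics <- independent_contrasts(rt, y)
    oracle <- gls_brownian(rt, y)
    expect_equal(mean(pics$contrast^2), oracle$rate_reml, tolerance = 1e-8)
    expect_equal(attr(pics, "root_value"), oracle$mu, tolerance = 1e-8)
  }
})

test_that("contrasts are invariant to tip reordering up to sign", {
  tr <- yule_tree(9, seed = 55)
  y <- withr::with_seed(9, setNames(rnorm(9), tr$tip.label))
  rot <- ape::rotate(tr, node = 11)
  a <- independent_contrasts(tr, y)
  b <- independent_contrasts(rot, y)
  expect_equal(sort(abs(a$contrast)), sort(abs(b$contrast)), tolerance = 1e-12)
})

test_that("zero branch lengths are rejected for contrasts", {
  tr <- parse_newick("((A:0,B:1):1,C:2);")
  expect_error(independent_contrasts(tr, c(A = 1, B = 2, C = 3)),
               "branch length")
})

test_that("regime annotations are readable from TSV and newick comments", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("tip\tregime\nA\tasymmetric\nB\tsymmetric", tmp)
  tv <- read_regime_tsv(tmp)
  expect_equal(tv[["A"]], "asymmetric")

  res <- parse_newick_regimes(
    "((A[&regime=asymmetric]:1,B[&regime=asymmetric]:1):1,C[&regime=symmetric]:2);")
  expect_equal(sort(res$tree$tip.label), c("A", "B", "C"))
  expect_equal(unname(res$tip_regimes[c("A", "C")]),
               c("asymmetric", "symmetric"))
})
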