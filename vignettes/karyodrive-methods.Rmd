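---
title: "Testing centromere-drive signatures in karyotype and CENH3 evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing centromere-drive signatures in karyotype and CENH3 evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyodrive)
```

## The scientific question

Asymmetric female meiosis — where only one of four meiotic products becomes
a gamete — creates an arena in which homologous centromeres compete for the
surviving product ("centromere drive"). Seed plants (angiosperms,
gymnosperms) have asymmetric female meiosis; bryophytes, lycophytes and
ferns retain all four products and therefore have no opportunity for drive.
Two comparative predictions follow:

1. lineages with drive opportunity should show a higher frequency of
   episodic positive selection on the centromeric histone **CENH3**, whose
   adaptive evolution is the classic signature of drive suppression; and
2. because centromere size constrains chromosome size, drive should
   accelerate the evolution of **chromosome size** itself.

`karyodrive` implements the full comparative machinery needed to test both
predictions on clade-level summaries, together with a seeded synthetic-data
generator so that every stage can be exercised, calibrated and validated
without any external data.

## Clade-level statistics

**Rate of chromosome-size evolution.** For each species the mean chromosome
size is the ratio of genome size to chromosome number, `2C / 2n` (Mb).
Within each clade these sizes are z-standardized (sample-sd denominator, the
`scale()` convention), phylogenetic independent contrasts are computed on
the clade's ultrametric species tree with the Felsenstein pruning recursion,
and the clade is summarized by the **median of the absolute contrasts**.
Because of the z-transform this statistic is invariant to affine
transformations of the raw trait; rescaling all branch lengths by `s`
divides it by `sqrt(s)`, so branch-length units (relative vs absolute time)
only shift all clades jointly.

**Frequency of positive selection on CENH3.** The package consumes
*tabulated* outputs of branch-level (aBSREL-style) and codon-level
(MEME-style) dN/dS tests — it does not re-run codon models. Per clade,

- `f_branch` = (# orthologous-group branches with uncorrected P < 0.05) /
  (# orthologous-group branches); paralogous subtrees are excluded from both
  counts via a user-supplied flag;
- `f_codon` = (# codons with P < 0.1) / (alignment length in codons);
- the composite frequency is the product `F = f_branch * f_codon`.

Both thresholds are strict inequalities; the defaults (0.05, 0.1) are the
exploratory-analysis conventions of the underlying selection tests, and no
multiple-testing correction is applied, deliberately. `F` is computed for
the full gene and separately for N- and C-terminal partitions when the
input tables provide them.

## The seven-model trait suite

Each clade-level response (the rate statistic, and `F` per region) is
modelled on the painted clade tree with two Brownian models and five
Ornstein-Uhlenbeck models:

| model | optimum theta | pull alpha | diffusion sigma^2 | k (2 regimes) |
|-------|--------------|------------|-------------------|---------------|
| BM1   | (root mean)  | —          | shared            | 2 |
| BMS   | (root mean)  | —          | per regime        | 3 |
| OU1   | shared       | shared     | shared            | 3 |
| OUM   | per regime   | shared     | shared            | 4 |
| OUMV  | per regime   | shared     | per regime        | 5 |
| OUMA  | per regime   | per regime | shared            | 5 |
| OUMVA | per regime   | per regime | per regime        | 6 |

Branch regimes (asymmetric / symmetric meiosis) are painted by Fitch
parsimony from tip states, ties resolved toward the parent state and the
root toward a user-supplied root regime; each branch carries its child
node's state.

The tip expectation is `W theta`, where row `i` of the weight matrix `W`
accumulates `e^{-A(t2 -> T)} (1 - e^{-alpha_r (t2 - t1)})` over the regime
segments of the root-to-tip path (`A` is the integrated pull over the
remaining path) plus a residual root weight `e^{-A(0 -> T)}` assigned to the
root regime's column; every row sums to 1. The covariance accumulates
`(sigma^2_s / 2 alpha_s)(1 - e^{-2 alpha_s l})` over shared-path segments,
attenuated along both private paths; with all `alpha = 0` this reduces to
`sum(sigma^2 l)` (the BM case). Correctness of both matrices is checked in
the test suite against Runge-Kutta integration of the piecewise OU moment
equations on random painted trees.

**Root handling.** The default fixes the root state at the root regime's
optimum with zero root variance (so OU models carry no extra root
parameter; parameter counts above follow this convention).
`root_mode = "stationary"` instead adds the root regime's stationary
variance `sigma^2 / (2 alpha)`. Both modes are exercised in the tests; the
choice is exposed because published analyses rarely state it, and the two
modes can change which model ranks best on small trees.

**Fitting.** theta (and the BM root mean) are generalized-least-squares
profiles at every likelihood evaluation; the remaining `(alpha, sigma^2)`
are optimized on the log scale with L-BFGS-B. Starts come from a
deterministic 5 x 5 grid — alpha log-spaced over `[1e-4/T, 50/T]` with `T`
the tree depth, sigma^2 multipliers around a Brownian-rate data scaling
(raised to `2 alpha var(y)` when the stationary regime binds) — and the
best few grid points are polished (2 by default; all grid objectives are
retained in the `restarts` element, so multimodality is visible). The
upper alpha bound corresponds to essentially instantaneous adaptation at
`alpha T = 50`; estimates landing there are flagged. Fits are deterministic
given the configuration.

**Model choice.** Models are ranked by AICc by default
(`AICc = AIC + 2k(k+1)/(n-k-1)`; with 27 clades the small-sample correction
matters), with plain AIC behind a switch. Akaike weights
`w = exp(-delta/2)/sum(exp(-delta/2))` and evidence ratios `w_best / w_m`
are reported; the *selected set* is the best model plus every model with an
evidence ratio below 3.0 — the configured rule of thumb — which is how "two
equally probable best models" arise. Criterion ties break toward fewer
parameters, then a fixed model order. Models whose AICc is undefined
(`n <= k + 1`) are excluded with a recorded reason.

**Inference on the optima.** The difference between regime optima is
assessed by parametric bootstrap: simulate tip data under the fitted MLEs
on the same tree and painting (multivariate normal via the Cholesky factor
of the model covariance), refit the same model (starting from the
generating MLEs), collect the per-regime theta estimates, and compare the
two bootstrap distributions with a two-sided Mann-Whitney test; 100
replicates by default. The test suite measures the realized size of this
procedure under a null scenario (see *Calibration results* below).

**Mann-Whitney test.** U from rank sums; exact P by enumeration when
`n1 n2 <= 100` and there are no ties, otherwise the normal approximation
with continuity and tie corrections. Two-sided throughout.

**PGLS.** Clade-level responses are also regressed on the regime indicator
(symmetric = 0, asymmetric = 1) by generalized least squares with the
Brownian correlation of the clade tree; Pagel's lambda scales the
off-diagonal entries (fixed at 1 by default, 0 gives OLS, maximum
likelihood estimation on [0, 1] behind a flag). Responses are square-root
transformed by default — the variance-stabilizing choice for frequencies
and non-negative rate statistics; t tests use `n - 2` degrees of freedom.

## The synthetic study system

`simulate_clade_system()` generates every input the pipeline consumes, from
one master seed (per-clade counter-derived sub-seeds, so adding clades never
perturbs earlier clades):

- a Yule clade-level tree (27 tips by default) painted 21 asymmetric / 6
  symmetric, the composition of the motivating study design;
- a clade-level trait drawn under a configurable generating model (OUM by
  default), used for parameter-recovery and power work;
- per-clade Yule species trees and karyotypes: log mean chromosome size
  evolves under a within-clade OU *turnover* process whose pull is
  regime-specific (defaults: alpha 0.1/My asymmetric vs 0.01/My symmetric
  at equal stationary log-variance), on species trees whose crown age is
  also regime-specific (60 My vs 160 My). `2n` is an even base count per
  clade with rare doublings (polyploidy-shaped noise), and `2C` is
  recomposed as size x `2n`;
- Bernoulli selection tables: branch and codon P-values drawn significant
  with regime-specific true rates (defaults chosen so the composite
  frequency lands near 0.007 asymmetric / 0.003 symmetric, the magnitudes
  reported for full-length CENH3).

Two generator choices deserve comment. First, the trait is simulated on the
log scale because chromosome sizes are positive and right-skewed; it is
exponentiated before the `2C/2n` decomposition. Second — and this is a
substantive design point — a *Gaussian Brownian rate difference cannot be
the mechanism* behind clade differences in the rate statistic: the
within-clade z-transform makes the distribution of median-|PIC| independent
of a BM sigma^2. What the statistic measures is tempo relative to
dispersion. The generator therefore encodes the regime effect the way it
can actually arise in data: faster mean-reverting turnover of chromosome
size, and younger crown ages, in drive-prone clades. Equivalently: passing
the recovery tests says the pipeline detects differences in evolutionary
tempo, not differences in a scale parameter that its own standardization
removes.

Presets: `null` (identical optima and identical species-level processes in
both regimes), `paper_like` (clade-level optima 0.118 / 0.058, the
study-like rate-of-evolution contrast), and `strong_effect` (optima 4
stationary standard deviations apart).

What the generator does *not* emulate: real clades share one global
phylogeny rather than independent Yule trees; genome-size measurement
error, intraspecific variation and non-random taxon sampling are absent;
selection-test P-values are drawn independently across branches and codons,
whereas real aBSREL/MEME outputs are correlated along the gene tree.
Passing the recovery loop therefore demonstrates correctness of the
statistical machinery under the stated generating processes, not robustness
to every pathology of empirical data.

## Numerical choices and degenerate inputs

- Polytomies are rejected by the contrast code; `resolve_polytomies()`
  opts in to bifurcation with inserted branches of `1e-8 x` tree depth.
  Silent resolution would silently change contrasts.
- Contrast sign is first-listed child minus second (deterministic); all
  downstream use takes absolute values.
- Unrooted trees are rejected rather than midpoint-rooted: the regime
  painting and the OU root handling both depend on the root.
- Clades need at least 3 species for a rate (two contrasts under a median);
  smaller clades, clades with zero trait variance, and tree/table species
  mismatches produce recorded skip/drop manifests, never silent omissions.
- Multiple karyotype records per species collapse to the median 2C and the
  modal 2n (smallest on ties); `2C_pg` columns convert at 978 Mb/pg.
- Zero-weight regimes (a painting that never uses a regime) make that
  regime's theta inestimable (`NA`) and the fit collapses to the nested
  single-regime model, which is also what the degenerate-painting test
  asserts.
- The optimization tolerance is L-BFGS-B's `factr = 1e7` on the profiled
  deviance; covariance factorizations failing positive-definiteness return
  `-Inf` likelihood inside the optimizer and an explicit error (with the
  smallest eigenvalue) in the user-facing constructors.

## Calibration results the suite computes

The acceptance tests in `tests/testthat/test-acceptance.R` verify, at study
scale: exact agreement of the OU moment matrices with ODE oracles
(relative 1e-5) and of PIC-based Brownian rates with GLS (1e-8);
closed-form likelihood values; theta recovery within +/-3 SE at n = 200 and
monotone error shrinkage over n in {50, 200, 800}; theta-varying models
winning model selection in >= 45/50 strong-effect replicates; convergence
of the composite selection frequency to the product of its Bernoulli
rates; and the realized size of the bootstrap Mann-Whitney theta test
under the null preset (200 datasets x 60 replicates). The last check is a
deliberate stress test of a procedure that compares two *bootstrap*
distributions as if they were independent samples — a known
pseudoreplication concern — and its outcome should be read from the test
run itself rather than assumed.

Problem sizes in the suite (tree sizes, replicate counts) are the package's
own calibration choices: large enough for the asymptotics being checked,
small enough to keep the full suite runnable on a laptop.

## Known limitations

- Two regimes are what the acceptance work exercises; the matrix algebra
  supports more, but >2-regime behaviour is untested territory.
- No measurement-error model for the tip responses; OU-based PGLS
  correlation structures and phylogenetic logistic regression are out of
  scope.
- The bootstrap theta test follows the published workflow; as the size
  check documents, comparing bootstrap distributions with a rank test can
  be strongly anti-conservative. PGLS provides the calibrated companion
  inference.
- Regime painting is parsimony-based; stochastic character mapping is not
  implemented.
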