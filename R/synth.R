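#' Simulate a seeded Yule (pure-birth) tree
#'
#' Pure-birth tree rescaled to a requested root-to-tip depth, so the result
#' is ultrametric by construction and deterministic per seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param depth root-to-tip depth after rescaling (default 1).
#' @param tip_prefix prefix for tip labels.
#' @return an ultrametric `phylo` with tips `<tip_prefix>1..n`.
#' @export
yule_tree <- function(n_tips, seed, depth = 1, tip_prefix = "t") {
  if (n_tips < 2) stop("a Yule tree needs at least 2 tips", call. = FALSE)
  tree <- withr::with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  d <- max(node_depths(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length * (depth / d)
  tree$tip.label <- paste0(tip_prefix, seq_len(n_tips))
  attr(tree, "polytomies") <- FALSE
  tree
}

#' Scenario configuration for the synthetic study system
#'
#' Defines every knob of the generator that emulates the study design:
#' a clade-level tree with a two-regime painting (21 asymmetric / 6 symmetric
#' clades by default), a clade-level trait evolving under a named generating
#' model, per-clade species trees with karyotypes whose log mean chromosome
#' size churns under regime-specific turnover (asymmetric clades: younger
#' radiations with faster mean-reverting tempo), and Bernoulli
#' selection-test tables with regime-specific true positive rates.
#'
#' @param seed master seed; all randomness derives from it via per-clade
#'   counter-based sub-seeds.
#' @param n_clades,n_symmetric clade-level tree size and number of clades
#'   painted symmetric.
#' @param clade_depth root-to-tip depth of the clade tree.
#' @param model generating model for the clade-level trait.
#' @param theta,alpha,sigma2 generating parameters (named
#'   `asymmetric`/`symmetric` vectors or scalars).
#' @param species_range min/max species per clade (drawn uniformly).
#' @param species_depth per-regime crown age of the species trees (time
#'   units; asymmetric radiations are younger by default, matching the
#'   contrast between angiosperm/gymnosperm clades and the ancient
#'   bryophyte/lycophyte/fern lineages).
#' @param log_size_root optimum of log mean chromosome size (log Mb).
#' @param log_size_alpha per-regime turnover rate (OU pull, 1/time) of the
#'   species-level log trait: drive-prone clades churn chromosome size
#'   faster.
#' @param log_size_sigma2 per-regime diffusion of the log trait; defaults
#'   keep the stationary log-variance equal across regimes so the regimes
#'   differ in tempo, not in dispersion.
#' @param base_2n_support support of clade base chromosome numbers (even).
#' @param doubling_prob per-species probability of a genome doubling.
#' @param p_branch,p_codon per-regime Bernoulli rates of positive selection
#'   at branch and codon level.
#' @param n_codons codon alignment length per clade.
#' @param paralog_frac fraction of gene-tree branches flagged paralogous.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(seed = 1,
                            n_clades = 27, n_symmetric = 6,
                            clade_depth = 1,
                            model = "OUM",
                            theta = c(asymmetric = 0.118, symmetric = 0.058),
                            alpha = 3,
                            sigma2 = 0.02,
                            species_range = c(5, 20),
                            species_depth = c(asymmetric = 60, symmetric = 160),
                            log_size_root = log(150),
                            log_size_alpha = c(asymmetric = 0.1, symmetric = 0.01),
                            log_size_sigma2 = c(asymmetric = 0.04, symmetric = 0.004),
                            base_2n_support = seq(4, 48, by = 2),
                            doubling_prob = 0.05,
                            p_branch = c(asymmetric = 0.14, symmetric = 0.10),
                            p_codon = c(asymmetric = 0.05, symmetric = 0.03),
                            n_codons = 150,
                            paralog_frac = 0.1) {
  cfg <- list(seed = seed, n_clades = n_clades, n_symmetric = n_symmetric,
              clade_depth = clade_depth, model = model, theta = theta,
              alpha = alpha, sigma2 = sigma2, species_range = species_range,
              log_size_root = log_size_root, species_depth = species_depth,
              log_size_alpha = log_size_alpha,
              log_size_sigma2 = log_size_sigma2,
              base_2n_support = base_2n_support,
              doubling_prob = doubling_prob,
              p_branch = p_branch, p_codon = p_codon, n_codons = n_codons,
              paralog_frac = paralog_frac)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  probs <- c(cfg$p_branch, cfg$p_codon, cfg$doubling_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_symmetric >= cfg$n_clades || cfg$n_symmetric < 1) {
    stop("need 1 <= n_symmetric < n_clades", call. = FALSE)
  }
  if (cfg$n_clades < 3) stop("need at least 3 clades", call. = FALSE)
  if (any(cfg$base_2n_support %% 2 != 0 | cfg$base_2n_support < 2)) {
    stop("2n support must be even integers >= 2", call. = FALSE)
  }
  if (cfg$n_codons < 1 || cfg$species_range[1] < 2) {
    stop("invalid counts in scenario config", call. = FALSE)
  }
  invisible(cfg)
}

# counter-based sub-seed: adding clades never perturbs earlier clades
sub_seed <- function(seed, clade_index, stream = 0L) {
  (seed * 1009L + clade_index * 7919L + stream * 104729L) %% .Machine$integer.max
}

#' Named scenario presets
#'
#' * `null`: both regimes share one clade-level optimum (type-I-error work).
#' * `paper_like`: study-shaped optima for the rate of chromosome-size
#'   evolution (asymmetric 0.118, symmetric 0.058).
#' * `strong_effect`: optima separated by 4 stationary standard deviations,
#'   for power and recovery checks.
#'
#' @param seed master seed stored in each preset.
#' @return named list of `scenario_config` objects.
#' @export
scenario_presets <- function(seed = 1) {
  stat_sd <- sqrt(0.02 / (2 * 3))   # sigma2 / (2 alpha) of the base config
  list(
    null = scenario_config(seed = seed,
                           theta = c(asymmetric = 0.09, symmetric = 0.09),
                           p_branch = c(asymmetric = 0.12, symmetric = 0.12),
                           p_codon = c(asymmetric = 0.04, symmetric = 0.04),
                           species_depth = c(asymmetric = 100, symmetric = 100),
                           log_size_alpha = c(asymmetric = 0.02, symmetric = 0.02),
                           log_size_sigma2 = c(asymmetric = 0.008, symmetric = 0.008)),
    paper_like = scenario_config(seed = seed),
    strong_effect = scenario_config(
      seed = seed,
      theta = c(asymmetric = 0.09 + 2 * stat_sd, symmetric = 0.09 - 2 * stat_sd))
  )
}

#' Simulate the full synthetic study system
#'
#' Produces every input the pipeline consumes, plus the generating truth:
#' a painted clade-level tree, a clade-level trait drawn under the
#' configured generating model, per-clade Yule species trees (regime-specific
#' crown ages), species karyotypes (log mean chromosome size under an OU
#' turnover process whose tempo differs by regime, even 2n with rare
#' doublings, 2C back-computed as size x 2n), and Bernoulli branch/codon
#' selection tables for three CENH3 regions.
#'
#' @param config a [scenario_config()].
#' @return list with `clade_tree`, `regimes` (`regime_map`), `clade_regime`
#'   (named vector), `clade_trait` (clade-level trait draw), `species_trees`
#'   (named list), `karyotypes` (species table), `branch_tab`, `codon_tab`,
#'   `length_tab` (selection tables), and `truth` (generating parameters).
#' @export
simulate_clade_system <- function(config = scenario_config()) {
  validate_scenario_config(config)
  seed <- config$seed
  n <- config$n_clades

  clade_tree <- yule_tree(n, seed = sub_seed(seed, 0L, 1L),
                          depth = config$clade_depth, tip_prefix = "clade")
  sym_tips <- withr::with_seed(sub_seed(seed, 0L, 2L),
                               sample(clade_tree$tip.label, config$n_symmetric))
  clade_regime <- stats::setNames(
    ifelse(clade_tree$tip.label %in% sym_tips, "symmetric", "asymmetric"),
    clade_tree$tip.label)
  regimes <- paint_regimes(clade_tree, clade_regime,
                           root_regime = "asymmetric",
                           levels = c("asymmetric", "symmetric"))
  clade_trait <- simulate_tips(clade_tree, regimes, config$model,
                               list(theta = config$theta, alpha = config$alpha,
                                    sigma2 = config$sigma2),
                               seed = sub_seed(seed, 0L, 3L))

  theta_r <- resolve_regime_param(config$theta, regimes$levels, "theta")
  depth_r <- resolve_regime_param(config$species_depth, regimes$levels,
                                  "species_depth")
  lsa_r <- resolve_regime_param(config$log_size_alpha, regimes$levels,
                                "log_size_alpha")
  lss_r <- resolve_regime_param(config$log_size_sigma2, regimes$levels,
                                "log_size_sigma2")
  pb_r <- resolve_regime_param(config$p_branch, regimes$levels, "p_branch")
  pc_r <- resolve_regime_param(config$p_codon, regimes$levels, "p_codon")

  species_trees <- list()
  kary_rows <- list()
  branch_rows <- list()
  codon_rows <- list()
  length_rows <- list()
  regions <- c("full", "N-terminal", "C-terminal")

  for (i in seq_len(n)) {
    cl <- clade_tree$tip.label[i]
    reg <- clade_regime[[cl]]
    ridx <- match(reg, regimes$levels)
    sp_choices <- seq(config$species_range[1], config$species_range[2])
    n_sp <- withr::with_seed(
      sub_seed(seed, i, 1L),
      sp_choices[sample.int(length(sp_choices), 1)])
    sp_tree <- yule_tree(n_sp, seed = sub_seed(seed, i, 2L),
                         depth = depth_r[ridx],
                         tip_prefix = paste0(cl, "_sp"))
    species_trees[[cl]] <- sp_tree

    # species log mean chromosome size: within-clade OU turnover, with the
    # regime controlling the tempo (pull) at equal stationary dispersion
    sp_reg <- paint_regimes(sp_tree,
                            stats::setNames(rep(reg, n_sp), sp_tree$tip.label),
                            root_regime = reg, levels = regimes$levels)
    log_size <- simulate_tips(sp_tree, sp_reg, "OU1",
                              list(theta = config$log_size_root,
                                   alpha = rep(lsa_r[ridx], 2),
                                   sigma2 = rep(lss_r[ridx], 2)),
                              seed = sub_seed(seed, i, 3L))
    size <- exp(log_size)
    kary <- withr::with_seed(sub_seed(seed, i, 4L), {
      supp <- config$base_2n_support
      base_2n <- supp[sample.int(length(supp), 1)]
      doubled <- stats::rbinom(n_sp, 1, config$doubling_prob)
      two_n <- base_2n * 2^doubled
      data.frame(species = sp_tree$tip.label, clade = cl, regime = reg,
                 two_c_mb = size * two_n, two_n = two_n,
                 stringsAsFactors = FALSE)
    })
    kary_rows[[cl]] <- kary

    n_branches <- 2 * n_sp - 2
    sel <- withr::with_seed(sub_seed(seed, i, 5L), {
      orth <- stats::rbinom(n_branches, 1, 1 - config$paralog_frac)
      sig_b <- stats::rbinom(n_branches, 1, pb_r[ridx])
      p_b <- ifelse(sig_b == 1, stats::runif(n_branches, 0, 0.05),
                    stats::runif(n_branches, 0.05, 1))
      omega <- ifelse(sig_b == 1, stats::rlnorm(n_branches, log(2), 0.5),
                      stats::rlnorm(n_branches, log(0.3), 0.6))
      branch <- data.frame(clade = cl,
                           branch_id = paste0(cl, "_b", seq_len(n_branches)),
                           omega = omega, p_value = p_b, orthologous = orth,
                           stringsAsFactors = FALSE)
      codon <- do.call(rbind, lapply(regions, function(rgn) {
        nc <- if (rgn == "full") config$n_codons else
          floor(config$n_codons / 2)
        sig_c <- stats::rbinom(nc, 1, pc_r[ridx])
        data.frame(clade = cl, region = rgn, codon_index = seq_len(nc),
                   p_value = ifelse(sig_c == 1, stats::runif(nc, 0, 0.1),
                                    stats::runif(nc, 0.1, 1)),
                   omega = ifelse(sig_c == 1,
                                  stats::rlnorm(nc, log(2), 0.5),
                                  stats::rlnorm(nc, log(0.3), 0.6)),
                   stringsAsFactors = FALSE)
      }))
      list(branch = branch, codon = codon)
    })
    branch_rows[[cl]] <- sel$branch
    codon_rows[[cl]] <- sel$codon
    length_rows[[cl]] <- data.frame(
      clade = cl, region = regions,
      n_codons = c(config$n_codons, floor(config$n_codons / 2),
                   floor(config$n_codons / 2)),
      stringsAsFactors = FALSE)
  }

  karyotypes <- build_karyotype_table(do.call(rbind, kary_rows))
  rownames(karyotypes) <- NULL

  list(clade_tree = clade_tree, regimes = regimes,
       clade_regime = clade_regime, clade_trait = clade_trait,
       species_trees = species_trees, karyotypes = karyotypes,
       branch_tab = do.call(rbind, branch_rows),
       codon_tab = do.call(rbind, codon_rows),
       length_tab = do.call(rbind, length_rows),
       truth = list(model = config$model, theta = config$theta,
                    alpha = config$alpha, sigma2 = config$sigma2,
                    species_depth = config$species_depth,
                    log_size_alpha = config$log_size_alpha,
                    log_size_sigma2 = config$log_size_sigma2,
                    p_branch = config$p_branch, p_codon = config$p_codon,
                    seed = config$seed))
}

#' Write a simulated system to the on-disk formats the pipeline reads
#'
#' Emits Newick trees, the karyotype TSV, regime TSV, the three selection
#' tables and `truth.json` into `dir`.
#'
#' @param system result of [simulate_clade_system()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_clade_system <- function(system, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    clade_tree = file.path(dir, "clade_tree.nwk"),
    regimes = file.path(dir, "clade_regimes.tsv"),
    karyotypes = file.path(dir, "karyotypes.tsv"),
    branch = file.path(dir, "branch_tests.tsv"),
    codon = file.path(dir, "codon_tests.tsv"),
    lengths = file.path(dir, "alignment_lengths.tsv"),
    truth = file.path(dir, "truth.json"))
  write_newick(system$clade_tree, paths[["clade_tree"]])
  for (cl in names(system$species_trees)) {
    write_newick(system$species_trees[[cl]],
                 file.path(dir, paste0("species_tree_", cl, ".nwk")))
  }
  utils::write.table(
    data.frame(tip = names(system$clade_regime),
               regime = unname(system$clade_regime)),
    paths[["regimes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  kary_out <- system$karyotypes
  names(kary_out)[names(kary_out) == "two_c_mb"] <- "2C_Mb"
  names(kary_out)[names(kary_out) == "two_n"] <- "2n"
  kary_out$mean_chrom_size <- NULL
  utils::write.table(kary_out, paths[["karyotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(system$branch_tab, paths[["branch"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(system$codon_tab, paths[["codon"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(system$length_tab, paths[["lengths"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(system$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
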