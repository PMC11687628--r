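#' Frequency of positively selected branches
#'
#' Number of orthologous-group branches with an uncorrected P below
#' `alpha_branch`, divided by the number of orthologous-group branches.
#' Branches flagged as paralogous are excluded from numerator and
#' denominator, so independent evolution of paralogues does not inflate the
#' statistic. Thresholding is a strict `<`; P-values exactly at the
#' threshold are not counted.
#'
#' @param p_values numeric vector of uncorrected branch-level P-values.
#' @param orthologous logical (or 0/1) vector flagging branches that belong
#'   to orthologous groups.
#' @param alpha_branch significance threshold, default 0.05.
#' @return list with `f_branch`, `n_significant`, `n_denominator`.
#' @export
branch_frequency <- function(p_values, orthologous = rep(TRUE, length(p_values)),
                             alpha_branch = 0.05) {
  stopifnot(length(p_values) == length(orthologous))
  check_pvals(p_values)
  if (!(alpha_branch > 0 && alpha_branch < 1)) {
    stop("`alpha_branch` must be in (0, 1)", call. = FALSE)
  }
  orthologous <- as.logical(orthologous)
  p <- p_values[orthologous]
  if (length(p) == 0) {
    stop("no orthologous-group branches: branch frequency undefined",
         call. = FALSE)
  }
  n_sig <- sum(p < alpha_branch)
  list(f_branch = n_sig / length(p), n_significant = n_sig,
       n_denominator = length(p))
}

#' Frequency of positively selected codons
#'
#' Number of codons with P below `alpha_codon` divided by the alignment
#' length in codons. Strict `<` at the threshold.
#'
#' @param p_values codon-level P-values (one per tested codon).
#' @param n_codons alignment length in codons (>= 1, >= number of records).
#' @param codon_index optional 1-based codon positions, validated against
#'   `n_codons` and checked for duplicates.
#' @param alpha_codon significance threshold, default 0.1.
#' @return list with `f_codon`, `n_significant`, `n_codons`.
#' @export
codon_frequency <- function(p_values, n_codons, codon_index = NULL,
                            alpha_codon = 0.1) {
  check_pvals(p_values)
  if (!(n_codons >= 1)) stop("`n_codons` must be >= 1", call. = FALSE)
  if (length(p_values) > n_codons) {
    stop("more codon records than codons in the alignment", call. = FALSE)
  }
  if (!is.null(codon_index)) {
    if (anyDuplicated(codon_index)) {
      stop("duplicated codon indices", call. = FALSE)
    }
    if (any(codon_index < 1 | codon_index > n_codons)) {
      stop("codon index outside 1..n_codons", call. = FALSE)
    }
  }
  n_sig <- sum(p_values < alpha_codon)
  list(f_codon = n_sig / n_codons, n_significant = n_sig, n_codons = n_codons)
}

#' Composite per-clade selection frequency
#'
#' The product of the branch-level and codon-level frequencies: a single
#' number per clade (and CENH3 region) summarizing how often the gene is
#' under episodic positive selection.
#'
#' @param f_branch,f_codon component frequencies in `[0, 1]`.
#' @return the product `F = f_branch * f_codon`.
#' @export
selection_frequency <- function(f_branch, f_codon) {
  stopifnot(all(f_branch >= 0 & f_branch <= 1),
            all(f_codon >= 0 & f_codon <= 1))
  f_branch * f_codon
}

check_pvals <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Per-clade composite selection frequencies from test tables
#'
#' Joins branch-level records, codon-level records and alignment lengths into
#' the per-(clade, region) composite frequency table used downstream.
#'
#' @param branch_tab data.frame with columns `clade, branch_id, omega,
#'   p_value, orthologous`.
#' @param codon_tab data.frame with columns `clade, region, codon_index,
#'   p_value` (region in `full`, `N-terminal`, `C-terminal`, or any labels
#'   supplied consistently with `length_tab`).
#' @param length_tab data.frame with columns `clade, region, n_codons`.
#' @param alpha_branch,alpha_codon significance thresholds (defaults 0.05 and
#'   0.1, strict `<`).
#' @return data.frame `clade, region, f_branch, f_codon, F, n_branch_denom,
#'   n_codons`.
#' @export
selection_frequency_table <- function(branch_tab, codon_tab, length_tab,
                                      alpha_branch = 0.05, alpha_codon = 0.1) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(what, " table missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  need(branch_tab, c("clade", "p_value", "orthologous"), "branch")
  need(codon_tab, c("clade", "region", "codon_index", "p_value"), "codon")
  need(length_tab, c("clade", "region", "n_codons"), "alignment-length")

  rows <- lapply(seq_len(nrow(length_tab)), function(i) {
    cl <- length_tab$clade[i]
    rg <- length_tab$region[i]
    nc <- length_tab$n_codons[i]
    b <- branch_tab[branch_tab$clade == cl, , drop = FALSE]
    cd <- codon_tab[codon_tab$clade == cl & codon_tab$region == rg, ,
                    drop = FALSE]
    fb <- branch_frequency(b$p_value, b$orthologous, alpha_branch)
    fc <- codon_frequency(cd$p_value, nc, cd$codon_index, alpha_codon)
    data.frame(clade = cl, region = rg,
               f_branch = fb$f_branch, f_codon = fc$f_codon,
               F = selection_frequency(fb$f_branch, fc$f_codon),
               n_branch_denom = fb$n_denominator, n_codons = nc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare dN/dS ratios between two groups
#'
#' Two-sided Mann-Whitney comparison of omega values pooled by meiosis
#' regime (branch-level or codon-level).
#'
#' @param omegas_a,omegas_b numeric vectors of dN/dS ratios for the two
#'   groups (each nonempty).
#' @return a `mann_whitney` result, see [mann_whitney()].
#' @export
compare_dnds_groups <- function(omegas_a, omegas_b) {
  mann_whitney(omegas_a, omegas_b)
}
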