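#' Mean chromosome size from genome size and chromosome count
#'
#' The species-level trait of the comparative analysis: holoploid genome size
#' (2C, in Mb) divided by the diploid chromosome number (2n).
#'
#' @param two_c numeric vector of 2C values in Mb (> 0).
#' @param two_n integer vector of 2n counts (>= 2).
#' @param species optional species names, used in validation messages.
#' @return numeric vector of mean chromosome sizes in Mb, order preserved.
#' @examples
#' mean_chromosome_size(1000, 10)   # 100 Mb
#' @export
mean_chromosome_size <- function(two_c, two_n, species = NULL) {
  if (length(two_c) != length(two_n)) {
    stop("`two_c` and `two_n` must have the same length", call. = FALSE)
  }
  lab <- function(i) if (is.null(species)) paste0("record ", i) else species[i]
  bad <- which(!is.finite(two_c) | two_c <= 0)
  if (length(bad) > 0) {
    stop("nonpositive or missing 2C for ", lab(bad[1]), call. = FALSE)
  }
  bad <- which(!is.finite(two_n) | two_n < 2 | two_n != round(two_n))
  if (length(bad) > 0) {
    stop("invalid 2n (must be an integer >= 2) for ", lab(bad[1]),
         call. = FALSE)
  }
  two_c / two_n
}

#' z-standardize a trait vector
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation, the
#' behaviour of base R's `scale()`. Used to put mean chromosome sizes on a
#' common scale within each clade before computing contrasts.
#'
#' @param values numeric vector, length >= 2, with nonzero dispersion.
#' @return z-scores (sample mean 0, sample sd 1).
#' @export
z_standardize <- function(values) {
  if (length(values) < 2) {
    stop("z-standardization needs at least 2 values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("z-standardization undefined: zero variance", call. = FALSE)
  }
  out <- (values - mean(values)) / s
  names(out) <- names(values)
  out
}

#' Read a species karyotype table
#'
#' Expects a delimited file with header columns `species, clade, regime,
#' 2C_Mb, 2n` (a `2C_pg` column may replace `2C_Mb` and is converted with
#' 1 pg = 978 Mb). Multiple records per species are collapsed to the median
#' 2C and the modal 2n (smallest on ties); collapses are reported in the
#' `"collapsed"` attribute.
#'
#' @param file path to a TSV/CSV file (separator sniffed from the extension).
#' @return data.frame with columns `species, clade, regime, two_c_mb, two_n,
#'   mean_chrom_size`.
#' @export
read_karyotype_table <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  build_karyotype_table(df)
}

#' Assemble and validate a karyotype table from a data.frame
#'
#' @param df data.frame with columns `species, clade, regime` and `2C_Mb`
#'   (or `two_c_mb`, or `2C_pg` which is converted at 978 Mb/pg) and `2n`
#'   (or `two_n`).
#' @return validated per-species table; see [read_karyotype_table()].
#' @export
build_karyotype_table <- function(df) {
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0) {
      stop("karyotype table must contain one of: ",
           paste(cands, collapse = ", "), call. = FALSE)
    }
    hit[1]
  }
  sp <- as.character(df[[pick(c("species"))]])
  clade <- as.character(df[[pick(c("clade"))]])
  regime <- as.character(df[[pick(c("regime"))]])
  ncol_2n <- pick(c("2n", "two_n"))
  if ("2C_Mb" %in% names(df) || "two_c_mb" %in% names(df)) {
    two_c <- as.numeric(df[[pick(c("2C_Mb", "two_c_mb"))]])
  } else {
    two_c <- as.numeric(df[[pick(c("2C_pg"))]]) * 978
  }
  two_n <- as.numeric(df[[ncol_2n]])

  out <- data.frame(species = sp, clade = clade, regime = regime,
                    two_c_mb = two_c, two_n = two_n,
                    stringsAsFactors = FALSE)
  collapsed <- character(0)
  if (anyDuplicated(out$species)) {
    dup <- unique(out$species[duplicated(out$species)])
    collapsed <- dup
    keep <- lapply(split(out, out$species), function(d) {
      tt <- table(d$two_n)
      best <- as.numeric(names(tt)[tt == max(tt)])
      d1 <- d[1, , drop = FALSE]
      d1$two_c_mb <- stats::median(d$two_c_mb)
      d1$two_n <- min(best)
      d1
    })
    out <- do.call(rbind, keep)
    rownames(out) <- NULL
    out <- out[order(match(out$species, sp)), , drop = FALSE]
  }
  out$mean_chrom_size <- mean_chromosome_size(out$two_c_mb, out$two_n,
                                              out$species)
  attr(out, "collapsed") <- collapsed
  out
}

#' Per-clade rate of chromosome-size evolution
#'
#' For every clade: take the species mean chromosome sizes (2C/2n),
#' z-standardize them within the clade, compute phylogenetic independent
#' contrasts on the clade tree pruned to the species shared by tree and
#' table, and summarize the clade by the median of the absolute contrasts.
#'
#' @param trees named list of clade-level species trees (`phylo`), names are
#'   clade names; or a single `phylo` if only one clade is analysed.
#' @param karyotypes karyotype table as returned by [read_karyotype_table()] /
#'   [build_karyotype_table()].
#' @param min_species minimum number of species (after intersecting tree and
#'   table) for a clade to be scored; smaller clades are skipped with a
#'   recorded reason. At least 3 keeps >= 2 contrasts under the median.
#' @return data.frame with one row per clade: `clade, regime, n_species,
#'   rate` (`rate` is `NA` for skipped clades); attributes `skipped` (named
#'   character of reasons) and `dropped_species` (per-clade manifest of
#'   tree/table mismatches).
#' @export
clade_rates <- function(trees, karyotypes, min_species = 3) {
  if (inherits(trees, "phylo")) {
    trees <- stats::setNames(list(trees), unique(karyotypes$clade)[1])
  }
  clades <- unique(karyotypes$clade)
  skipped <- character(0)
  dropped <- list()
  rows <- lapply(clades, function(cl) {
    tab <- karyotypes[karyotypes$clade == cl, , drop = FALSE]
    regime <- tab$regime[1]
    row <- data.frame(clade = cl, regime = regime, n_species = NA_integer_,
                      rate = NA_real_, stringsAsFactors = FALSE)
    if (!cl %in% names(trees)) {
      skipped[[cl]] <<- "no tree supplied for clade"
      return(row)
    }
    tree <- trees[[cl]]
    common <- intersect(tree$tip.label, tab$species)
    lost <- c(setdiff(tree$tip.label, tab$species),
              setdiff(tab$species, tree$tip.label))
    if (length(lost) > 0) dropped[[cl]] <<- lost
    row$n_species <- length(common)
    if (length(common) < min_species) {
      skipped[[cl]] <<- sprintf("only %d species shared by tree and table (min %d)",
                                length(common), min_species)
      return(row)
    }
    sub <- prune_to_taxa(tree, common)
    sizes <- stats::setNames(tab$mean_chrom_size, tab$species)[common]
    z <- tryCatch(z_standardize(sizes), error = function(e) NULL)
    if (is.null(z)) {
      skipped[[cl]] <<- "zero trait variance within clade"
      return(row)
    }
    pics <- independent_contrasts(sub, z)
    row$rate <- stats::median(abs(pics$contrast))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "dropped_species") <- dropped
  out
}
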