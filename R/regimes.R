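#' Paint branch regimes on a phylogeny by Fitch parsimony
#'
#' Assigns a categorical regime (here typically `asymmetric` vs `symmetric`
#' meiosis) to every branch of a rooted tree from the tip states. Internal
#' states are reconstructed with the Fitch small-parsimony pass: intersections
#' (else unions) of child state sets bottom-up, then ties broken top-down to
#' the parent's assigned state, with the root resolved to `root_regime` when
#' its set is ambiguous. Each branch carries the regime of its child node.
#'
#' @param tree a rooted `phylo` object.
#' @param tip_regimes named character vector mapping every tip label to a
#'   regime.
#' @param root_regime regime assigned to the root when parsimony leaves it
#'   ambiguous; must be one of the regimes in `levels`.
#' @param levels regime alphabet; defaults to the sorted unique values of
#'   `tip_regimes` plus `root_regime`.
#' @return a `regime_map` object: list with `edge_regime` (character, one per
#'   edge, in `tree$edge` order), `root_regime`, `levels`, and `node_regime`
#'   (per-node reconstruction, tips first).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' paint_regimes(tr, c(A = "asymmetric", B = "asymmetric", C = "symmetric"),
#'               root_regime = "symmetric")
#' @export
paint_regimes <- function(tree, tip_regimes, root_regime,
                          levels = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.null(names(tip_regimes))) {
    stop("`tip_regimes` must be named by tip label", call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, names(tip_regimes))
  if (length(missing) > 0) {
    stop("tips without a regime: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tip_regimes <- tip_regimes[tree$tip.label]
  if (is.null(levels)) {
    levels <- sort(unique(c(as.character(tip_regimes), root_regime)))
  }
  bad <- setdiff(unique(c(as.character(tip_regimes), root_regime)), levels)
  if (length(bad) > 0) {
    stop("regime(s) not in alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # state sets as lists of character vectors
  sets <- vector("list", nnode)
  sets[seq_len(ntip)] <- as.list(as.character(tip_regimes))

  post <- ape::reorder.phylo(tree, "postorder")
  children <- split(post$edge[, 2], post$edge[, 1])
  # bottom-up Fitch pass (postorder edge ordering guarantees children first)
  for (node in unique(post$edge[, 1])) {
    kid_sets <- sets[children[[as.character(node)]]]
    inter <- Reduce(intersect, kid_sets)
    sets[[node]] <- if (length(inter) > 0) inter else Reduce(union, kid_sets)
  }

  assigned <- character(nnode)
  assigned[seq_len(ntip)] <- as.character(tip_regimes)
  root_set <- sets[[root]]
  assigned[root] <- if (length(root_set) == 1) root_set else {
    if (root_regime %in% root_set) root_regime else root_set[1]
  }
  # top-down tie resolution in preorder
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[k, 1]
    child <- pre$edge[k, 2]
    if (child <= ntip) next
    s <- sets[[child]]
    assigned[child] <- if (length(s) == 1) s else {
      if (assigned[parent] %in% s) assigned[parent] else s[1]
    }
  }

  structure(
    list(edge_regime = assigned[tree$edge[, 2]],
         node_regime = assigned,
         root_regime = root_regime,
         levels = levels),
    class = "regime_map"
  )
}

#' @export
print.regime_map <- function(x, ...) {
  tab <- table(factor(x$edge_regime, levels = x$levels))
  cat("Regime painting:", length(x$edge_regime), "branches,",
      length(x$levels), "regimes\n")
  for (lv in x$levels) cat("  ", lv, ": ", tab[[lv]], " branches\n", sep = "")
  cat("  root regime:", x$root_regime, "\n")
  invisible(x)
}

# Number of regime changes implied by a painting (parent vs child state).
regime_changes <- function(tree, node_regime) {
  sum(node_regime[tree$edge[, 1]] != node_regime[tree$edge[, 2]])
}

#' Read tip regimes from a two-column TSV
#'
#' Expected columns: `tip` (or `species`) and `regime`.
#'
#' @param file path to a tab-separated file with a header.
#' @return named character vector tip -> regime.
#' @export
read_regime_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  tipcol <- intersect(c("tip", "species"), names(df))
  if (length(tipcol) == 0 || !"regime" %in% names(df)) {
    stop("regime file must have columns `tip` (or `species`) and `regime`",
         call. = FALSE)
  }
  stats::setNames(as.character(df$regime), as.character(df[[tipcol[1]]]))
}

#' Extract tip regimes from extended-Newick comments
#'
#' Reads annotations of the form `tipname[&regime=asymmetric]:1.23` and
#' returns both the cleaned tree and the tip regime vector.
#'
#' @param text a Newick string with optional `[&regime=...]` comments.
#' @return list with `tree` (comments stripped, parsed) and `tip_regimes`
#'   (named character vector; tips without annotation are absent).
#' @export
parse_newick_regimes <- function(text) {
  m <- gregexpr("([A-Za-z0-9_.|-]+)\\[&regime=([A-Za-z0-9_-]+)\\]", text)[[1]]
  tips <- character(0)
  regs <- character(0)
  if (m[1] != -1) {
    pieces <- regmatches(text, gregexpr(
      "([A-Za-z0-9_.|-]+)\\[&regime=([A-Za-z0-9_-]+)\\]", text))[[1]]
    tips <- sub("\\[.*$", "", pieces)
    regs <- sub("^.*\\[&regime=", "", sub("\\]$", "", pieces))
  }
  clean <- gsub("\\[&[^]]*\\]", "", text)
  list(tree = parse_newick(text = clean),
       tip_regimes = stats::setNames(regs, tips))
}
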