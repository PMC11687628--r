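#' Parse a Newick string into a rooted phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object; all downstream functions in this package consume that
#' container. Every non-root edge must carry a branch length; polytomies are
#' retained but flagged via the `"polytomies"` attribute so that callers that
#' require bifurcating trees (e.g. [independent_contrasts()]) can direct the
#' user to [resolve_polytomies()].
#'
#' @param text a Newick string (terminated by `;`). Exactly one of `text` /
#'   `file` must be given.
#' @param file path to a file containing one Newick tree.
#' @return a rooted `phylo` object with attribute `polytomies` (logical).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  }
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  offset <- newick_syntax_offset(text)
  if (!is.na(offset)) {
    stop(sprintf("malformed Newick string at character %d", offset),
         call. = FALSE)
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string (parser failure)", call. = FALSE)
  }
  validate_phylogeny(tree)
  attr(tree, "polytomies") <- !ape::is.binary(tree)
  tree
}

# Light syntactic scan: returns the 1-based character offset of the first
# structural violation (unbalanced parenthesis, text after ';', missing ';'),
# or NA if the scan passes.  Finer-grained errors are left to the parser.
newick_syntax_offset <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_comment <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_comment) {
      if (ch == "]") in_comment <- FALSE
      next
    }
    if (ch == "[") { in_comment <- TRUE; next }
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
    if (ch == ";") {
      if (depth != 0L) return(i)
      if (i < length(chars) && any(nzchar(trimws(chars[(i + 1):length(chars)])))) {
        return(i + 1L)
      }
      return(NA_integer_)
    }
  }
  length(chars) + 1L  # no terminating ';' (or unclosed '(' / '[')
}

# Shared structural checks for trees entering the pipeline.
validate_phylogeny <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; they are required", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    bad <- tree$edge[which(is.na(tree$edge.length))[1], 2]
    stop(sprintf("missing branch length on the edge to node '%s'",
                 node_display_label(tree, bad)), call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    bad <- tree$edge[which(tree$edge.length < 0)[1], 2]
    stop(sprintf("negative branch length on the edge to node '%s'",
                 node_display_label(tree, bad)), call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicated tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; a rooted tree is required (regime painting and ",
         "OU weights depend on the root)", call. = FALSE)
  }
  invisible(tree)
}

node_display_label <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) tree$tip.label[node] else paste0("node#", node)
}

#' Write a phylogeny to a Newick string
#'
#' @param tree a `phylo` object.
#' @param file optional path; if given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 15)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Prune a phylogeny to a set of tips
#'
#' Returns the induced subtree on `keep`: unsampled tips are dropped,
#' resulting degree-2 internal nodes are collapsed with their branch lengths
#' summed, so root-to-tip depths of the retained tips are unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 1).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) < 1) stop("`keep` must contain at least one tip label", call. = FALSE)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    stop("tip labels not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep) == length(tree$tip.label)) {
    return(tree)
  }
  out <- ape::keep.tip(tree, keep)
  attr(out, "polytomies") <- !ape::is.binary(out)
  out
}

#' Check whether a tree is ultrametric
#'
#' A tree is called ultrametric here when the spread of root-to-tip depths,
#' relative to the maximum depth, does not exceed `rel_tol`.
#'
#' @param tree a `phylo` object.
#' @param rel_tol relative tolerance on `(max depth - min depth) / max depth`.
#' @return list with `ultrametric` (logical) and `max_deviation` (the relative
#'   spread actually observed).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  dmax <- max(depths)
  dev <- if (dmax > 0) (dmax - min(depths)) / dmax else 0
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

# Root-to-node path lengths for all nodes (root depth 0).
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Resolve polytomies to bifurcations
#'
#' Multifurcations are expanded into cherries connected by branches of length
#' `eps_frac * tree depth` (ape's `multi2di` with zero-length branches, then
#' the zeros replaced). This changes independent contrasts, so it is an
#' explicit opt-in rather than something done silently by the contrast code.
#'
#' @param tree a `phylo` object.
#' @param eps_frac fraction of tree depth used as the inserted branch length.
#' @return a bifurcating `phylo` object.
#' @export
resolve_polytomies <- function(tree, eps_frac = 1e-8) {
  if (ape::is.binary(tree)) return(tree)
  depth <- max(node_depths(tree))
  out <- ape::multi2di(tree, random = FALSE)
  eps <- eps_frac * if (depth > 0) depth else 1
  out$edge.length[out$edge.length == 0] <- eps
  attr(out, "polytomies") <- FALSE
  out
}
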