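#' Phylogenetic independent contrasts
#'
#' Felsenstein's (1985) pruning recursion. At each internal node with child
#' values x1, x2 reached by (adjusted) branch lengths v1, v2:
#' contrast = (x1 - x2) / sqrt(v1 + v2), the node value is the weighted
#' average (x1/v1 + x2/v2) / (1/v1 + 1/v2), and the node's parent edge is
#' lengthened by v1*v2/(v1 + v2). Contrasts are returned in postorder
#' (deterministic) with the sign convention first-listed child minus second.
#'
#' @param tree a fully bifurcating rooted `phylo` with all branch lengths > 0.
#'   Polytomous trees are rejected; see [resolve_polytomies()].
#' @param tip_values named numeric vector covering every tip label.
#' @return a `contrast_set`: data.frame with one row per internal node
#'   (postorder), columns `node` (ape node id), `contrast` (standardized),
#'   `variance` (sum of adjusted branch lengths), `node_value` (ancestral
#'   estimate). The root estimate is `attr(, "root_value")`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' independent_contrasts(tr, c(A = 2, B = 0, C = 4))
#' @export
independent_contrasts <- function(tree, tip_values) {
  ntip <- ape::Ntip(tree)
  if (!ape::is.binary(tree)) {
    stop("tree contains polytomies; resolve them explicitly with ",
         "resolve_polytomies() before computing contrasts", call. = FALSE)
  }
  if (any(tree$edge.length <= 0)) {
    stop("all branch lengths must be > 0 for contrasts (zero-length edge ",
         "found); see resolve_polytomies(eps_frac=) for inserted edges",
         call. = FALSE)
  }
  if (is.null(names(tip_values))) {
    stop("`tip_values` must be named by tip label", call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing) > 0) {
    stop("tips without a value: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (ntip < 2) stop("at least two tips are required", call. = FALSE)

  nnode <- ntip + tree$Nnode
  x <- numeric(nnode)
  x[seq_len(ntip)] <- as.numeric(tip_values[tree$tip.label])
  # adjusted length of the edge above each node
  v <- numeric(nnode)
  post <- ape::reorder.phylo(tree, "postorder")
  v[post$edge[, 2]] <- post$edge.length

  m <- tree$Nnode
  out_node <- integer(m)
  out_contrast <- numeric(m)
  out_var <- numeric(m)
  out_value <- numeric(m)
  i <- 0L
  # children in the tree's own (cladewise) listing order -> sign convention
  first_child <- integer(nnode)
  second_child <- integer(nnode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    if (first_child[p] == 0L) first_child[p] <- tree$edge[k, 2]
    else second_child[p] <- tree$edge[k, 2]
  }
  # visit each internal node once both its child edges have been seen while
  # scanning the postorder edge list; postorder guarantees a child's own
  # subtree is complete before the edge above it appears
  seen <- integer(nnode)
  node_order <- integer(m)
  j <- 0L
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]
    seen[p] <- seen[p] + 1L
    if (seen[p] == 2L) { j <- j + 1L; node_order[j] <- p }
  }
  for (node in node_order) {
    c1 <- first_child[node]
    c2 <- second_child[node]
    v1 <- v[c1]; v2 <- v[c2]
    i <- i + 1L
    out_node[i] <- node
    out_var[i] <- v1 + v2
    out_contrast[i] <- (x[c1] - x[c2]) / sqrt(v1 + v2)
    x[node] <- (x[c1] / v1 + x[c2] / v2) / (1 / v1 + 1 / v2)
    out_value[i] <- x[node]
    v[node] <- v[node] + v1 * v2 / (v1 + v2)
  }
  res <- data.frame(node = out_node, contrast = out_contrast,
                    variance = out_var, node_value = out_value)
  class(res) <- c("contrast_set", "data.frame")
  attr(res, "root_value") <- x[ntip + 1L]
  res
}
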