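#' Species tree with deterministic post-order node indexing
#'
#' A `species_tree` is a rooted, strictly binary tree whose tips are genome
#' identifiers. Nodes are indexed 1..2N-1 in post-order (children always
#' before their parent, root last), the indexing shared by every
#' presence/absence tree (TOG) built on the same scaffold.
#'
#' @param x A newick string, a file path to a newick file, or an
#'   [ape::phylo] object.
#' @return An object of class `species_tree`: a list with elements
#'   `n_leaves`, `n_nodes`, `parent` (integer, `NA` at the root), `children`
#'   (`n_nodes` x 2 integer matrix, `NA` rows at leaves), `is_leaf`,
#'   `labels` (genome id at leaves, `""` at internal nodes), `root`
#'   (always `n_nodes`) and `newick`.
#' @examples
#' tr <- species_tree("((A,B),(C,D));")
#' tr$n_nodes   # 7
#' @export
species_tree <- function(x) {
  if (inherits(x, "species_tree")) return(x)
  if (inherits(x, "phylo")) {
    phy <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    txt <- if (grepl(";", x)) x else paste0(readLines(x, warn = FALSE), collapse = "")
    phy <- ape::read.tree(text = txt)
    if (is.null(phy)) stop("could not parse newick input")
  }
  n <- length(phy$tip.label)
  if (n < 2L) stop("species tree needs at least 2 leaves")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf name in species tree: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  # children lists in ape numbering (tips 1..n, internals n+1..)
  kids <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(n + phy$Nnode)))
  deg <- lengths(kids)
  if (any(deg[deg > 0L] != 2L))
    stop("non-binary node in species tree (every internal node must have exactly 2 children)")
  root_ape <- n + 1L
  # iterative post-order DFS with deterministic (left-to-right) child order
  post <- integer(0L)
  stack <- list(list(node = root_ape, visited = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$visited || deg[top$node] == 0L) {
      post <- c(post, top$node)
    } else {
      stack[[length(stack) + 1L]] <- list(node = top$node, visited = TRUE)
      ch <- kids[[top$node]]
      stack[[length(stack) + 1L]] <- list(node = ch[2L], visited = FALSE)
      stack[[length(stack) + 1L]] <- list(node = ch[1L], visited = FALSE)
    }
  }
  n_nodes <- 2L * n - 1L
  stopifnot(length(post) == n_nodes)
  idx <- integer(n + phy$Nnode)   # ape number -> post-order index
  idx[post] <- seq_len(n_nodes)
  parent <- rep(NA_integer_, n_nodes)
  children <- matrix(NA_integer_, n_nodes, 2L)
  for (a in post) {
    if (deg[a] > 0L) {
      ch <- idx[kids[[a]]]
      children[idx[a], ] <- ch
      parent[ch] <- idx[a]
    }
  }
  is_leaf <- is.na(children[, 1L])
  labels <- character(n_nodes)
  labels[idx[seq_len(n)]] <- phy$tip.label
  structure(list(
    n_leaves = n, n_nodes = n_nodes, parent = parent, children = children,
    is_leaf = is_leaf, labels = labels, root = n_nodes,
    newick = ape::write.tree(phy)
  ), class = "species_tree")
}

#' Read a rooted binary species tree from a newick file
#'
#' @param path Path to a newick file. Non-binary trees and duplicate leaf
#'   names are rejected.
#' @return A [species_tree()] object.
#' @export
read_species_tree <- function(path) species_tree(path)

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", x$n_leaves, "genomes,", x$n_nodes, "nodes (post-order indexed)\n")
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Leaf node indices of a species tree
#' @param tree A [species_tree()].
#' @return Integer vector of post-order indices of the leaves.
#' @export
st_leaves <- function(tree) which(tree$is_leaf)

#' Map genome ids to leaf node indices
#' @param tree A [species_tree()].
#' @param genomes Character vector of genome ids (must all be leaf labels).
#' @return Integer vector of leaf node indices.
#' @export
st_leaf_index <- function(tree, genomes) {
  i <- match(genomes, tree$labels)
  if (anyNA(i)) stop("unknown genome id(s): ", paste(genomes[is.na(i)], collapse = ", "))
  i
}

#' Leaves in the subtree rooted at a node
#' @param tree A [species_tree()].
#' @param node Post-order node index.
#' @return Integer vector of leaf indices below (or equal to) `node`.
#' @export
st_descendant_leaves <- function(tree, node) {
  acc <- integer(0L); stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (tree$is_leaf[v]) acc <- c(acc, v)
    else stack <- c(stack, tree$children[v, ])
  }
  sort(acc)
}

# all descendants (excluding the node itself)
st_descendants <- function(tree, node) {
  acc <- integer(0L); stack <- if (tree$is_leaf[node]) integer(0L) else tree$children[node, ]
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    acc <- c(acc, v)
    if (!tree$is_leaf[v]) stack <- c(stack, tree$children[v, ])
  }
  acc
}

# all ancestors (excluding the node itself), root-most last
st_ancestors <- function(tree, node) {
  acc <- integer(0L); v <- tree$parent[node]
  while (!is.na(v)) { acc <- c(acc, v); v <- tree$parent[v] }
  acc
}
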