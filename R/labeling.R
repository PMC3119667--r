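#' Minimum-flip labeling of trees of ortholog groups (TOGs)
#'
#' @description
#' Every SOG of a family is projected onto the species tree as a TOG: a
#' binary labeling of the leaves (1 = the SOG contains a gene of that
#' genome). The labeling problem asks for 0/1 labels at all internal nodes
#' of all K TOGs of the family minimizing the total number of *flips*
#' (edges whose endpoints carry different labels; each flip is a gene
#' birth, duplication or loss), subject to
#'
#' * the **intratree constraint** (per TOG): a node labeled 0 below a
#'   1-labeled ancestor has no 1-labeled descendant — a lost gene is never
#'   regained; and
#' * the **intertree constraint** (across the family's TOGs): the nodes
#'   labeled 1 in at least one TOG form a connected subtree of the species
#'   tree — the family is born only once. Connectivity of the union 1-set
#'   is equivalent to the pathwise formulation because paths in a tree are
#'   unique.
#'
#' Three interchangeable solvers are provided: an exhaustive search
#' ([label_exhaustive()], the reference oracle), a dynamic program over
#' per-node label vectors ([label_node_centric()]) and a dynamic program
#' over running union labelings ([label_tree_centric()]). All three return
#' the same optimal flip count; the particular optimal labeling returned is
#' a deterministic representative and may differ between solvers.
#'
#' @param tree A [species_tree()].
#' @param presence A K x N binary matrix: row per TOG, column per genome
#'   (colnames must match the tree's leaf labels); entry 1 means the SOG
#'   has a gene from that genome. Every TOG needs at least one 1.
#' @return For `tog_problem()`: a `tog_problem` object holding the tree and
#'   the K x `n_nodes` label matrix (internal columns `NA`).
#' @name tog-labeling
NULL

#' @rdname tog-labeling
#' @export
tog_problem <- function(tree, presence) {
  tree <- species_tree(tree)
  if (is.null(dim(presence))) presence <- matrix(presence, nrow = 1L,
                                                 dimnames = list(NULL, names(presence)))
  if (is.null(colnames(presence)))
    stop("presence matrix needs genome ids as column names")
  if (!all(presence %in% c(0, 1))) stop("presence entries must be 0/1")
  if (any(rowSums(presence) == 0))
    stop("all-zero TOG: every TOG must contain at least one gene")
  leaf_idx <- st_leaf_index(tree, colnames(presence))
  if (length(leaf_idx) != tree$n_leaves)
    stop("presence matrix must cover every genome of the species tree")
  K <- nrow(presence)
  labels <- matrix(NA_real_, K, tree$n_nodes)
  labels[, leaf_idx] <- presence
  structure(list(tree = tree, labels = labels, K = K), class = "tog_problem")
}

#' Count flips of a fully labeled TOG
#'
#' @param labels Numeric 0/1 vector of length `n_nodes` (one TOG), or a
#'   K x `n_nodes` matrix (summed over rows).
#' @param tree The [species_tree()].
#' @return Integer number of edges whose endpoint labels differ.
#' @export
count_flips <- function(labels, tree) {
  if (is.matrix(labels))
    return(sum(vapply(seq_len(nrow(labels)), function(k)
      count_flips(labels[k, ], tree), numeric(1L))))
  if (anyNA(labels)) stop("labeling is incomplete (NA labels)")
  v <- which(!is.na(tree$parent))
  sum(abs(labels[v] - labels[tree$parent[v]]))
}

#' Check the intratree constraint of one labeled TOG
#' @inheritParams count_flips
#' @return `TRUE` iff no 0-labeled node has both a 1-labeled ancestor and a
#'   1-labeled descendant.
#' @export
check_intratree <- function(labels, tree) {
  if (anyNA(labels)) stop("labeling is incomplete (NA labels)")
  sub1 <- logical(tree$n_nodes)   # any 1 strictly below
  for (v in seq_len(tree$n_nodes)) if (!tree$is_leaf[v]) {
    ch <- tree$children[v, ]
    sub1[v] <- any(labels[ch] == 1) || any(sub1[ch])
  }
  anc1 <- logical(tree$n_nodes)   # any 1 strictly above
  for (v in rev(seq_len(tree$n_nodes))) if (!tree$is_leaf[v]) {
    ch <- tree$children[v, ]
    anc1[ch] <- anc1[v] || labels[v] == 1
  }
  !any(labels == 0 & anc1 & sub1)
}

#' Check the intertree constraint of a family's labeled TOGs
#' @param labels K x `n_nodes` 0/1 matrix of fully labeled TOGs.
#' @param tree The [species_tree()].
#' @return `TRUE` iff the union 1-set (nodes labeled 1 in at least one TOG)
#'   induces a connected subtree.
#' @export
check_intertree <- function(labels, tree) {
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  if (anyNA(labels)) stop("labeling is incomplete (NA labels)")
  ones_connected(apply(labels, 2L, max) == 1, tree)
}

# a set of nodes (logical vector) induces a connected subtree:
# in a forest, #components = #nodes - #edges-within
ones_connected <- function(ones, tree) {
  n1 <- sum(ones)
  if (n1 == 0L) return(TRUE)
  v <- which(!is.na(tree$parent))
  edges_in <- sum(ones[v] & ones[tree$parent[v]])
  (n1 - edges_in) == 1L
}

# all intratree-feasible completions of one TOG's leaf labels:
# list(labels = n_feas x n_nodes matrix, flips = vector)
enumerate_feasible <- function(tree, leaf_row) {
  internal <- which(!tree$is_leaf)
  ni <- length(internal)
  n_lab <- 2L^ni
  L <- matrix(rep(leaf_row, each = n_lab), n_lab, tree$n_nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), ni)))[, seq_len(ni), drop = FALSE]
  L[, internal] <- grid
  # vectorized intratree check over all rows
  sub1 <- matrix(FALSE, n_lab, tree$n_nodes)
  for (v in seq_len(tree$n_nodes)) if (!tree$is_leaf[v]) {
    ch <- tree$children[v, ]
    sub1[, v] <- (L[, ch[1L]] == 1) | (L[, ch[2L]] == 1) | sub1[, ch[1L]] | sub1[, ch[2L]]
  }
  anc1 <- matrix(FALSE, n_lab, tree$n_nodes)
  for (v in rev(seq_len(tree$n_nodes))) if (!tree$is_leaf[v]) {
    ch <- tree$children[v, ]
    a <- anc1[, v] | (L[, v] == 1)
    anc1[, ch[1L]] <- a; anc1[, ch[2L]] <- a
  }
  bad <- rowSums(L == 0 & anc1 & sub1) > 0
  L <- L[!bad, , drop = FALSE]
  e <- which(!is.na(tree$parent))
  flips <- rowSums(abs(L[, e, drop = FALSE] - L[, tree$parent[e], drop = FALSE]))
  list(labels = L, flips = flips)
}

#' Exhaustive-search reference solver
#'
#' Enumerates every intratree-feasible labeling of every TOG and every
#' combination across TOGs, keeping the minimum-flip combination whose
#' union 1-set is connected. Exact by construction; guarded to small
#' instances (`K * (N - 1) <= 24`).
#'
#' @param problem A [tog_problem()].
#' @param intertree If `FALSE`, drop the intertree constraint (diagnostic
#'   use: quantifies the cost the constraint adds).
#' @return A `tog_labeling` solution: list with `labels` (K x `n_nodes`
#'   0/1 matrix), `total_flips` and `solver`.
#' @export
label_exhaustive <- function(problem, intertree = TRUE) {
  tree <- problem$tree; K <- problem$K
  if (K * (tree$n_leaves - 1L) > 24L)
    stop("instance too large for exhaustive search (K*(N-1) > 24)")
  feas <- lapply(seq_len(K), function(k) enumerate_feasible(tree, problem$labels[k, ]))
  idx <- do.call(expand.grid, lapply(feas, function(f) seq_along(f$flips)))
  tot <- Reduce(`+`, lapply(seq_len(K), function(k) feas[[k]]$flips[idx[, k]]))
  if (intertree) {
    U <- Reduce(`|`, lapply(seq_len(K), function(k)
      feas[[k]]$labels[idx[, k], , drop = FALSE] == 1))
    n1 <- rowSums(U)
    e <- which(!is.na(tree$parent))
    ein <- rowSums(U[, e, drop = FALSE] & U[, tree$parent[e], drop = FALSE])
    ok <- (n1 - ein) == 1L
  } else ok <- rep(TRUE, nrow(idx))
  if (!any(ok)) stop("no feasible labeling (cannot occur when every TOG has a 1-leaf)")
  best <- which(ok & tot == min(tot[ok]))
  if (length(best) > 1L) {   # deterministic representative: prefer 0 at the
    key <- vapply(best, function(b) {     # root, then lexicographic labels
      rows <- vapply(seq_len(K), function(k)
        paste(feas[[k]]$labels[idx[b, k], ], collapse = ""), "")
      roots <- paste(substr(rows, tree$root, tree$root), collapse = "")
      paste(roots, paste(rows, collapse = "|"))
    }, "")
    best <- best[order(key)][1L]
  }
  labels <- t(vapply(seq_len(K), function(k)
    feas[[k]]$labels[idx[best, k], ], numeric(tree$n_nodes)))
  new_solution(labels, tree, "exhaustive")
}

new_solution <- function(labels, tree, solver) {
  structure(list(labels = labels, total_flips = count_flips(labels, tree),
                 solver = solver), class = "tog_labeling")
}

#' @export
print.tog_labeling <- function(x, ...) {
  cat("tog_labeling (", x$solver, "): ", nrow(x$labels), " TOG(s), ",
      x$total_flips, " flip(s)\n", sep = "")
  invisible(x)
}

## ----- node-centric dynamic program -------------------------------------

# Extended per-TOG labels: 0 = ZERO (0 here, all descendants 0),
# 1 = PENDING (0 here, some descendant 1), 2 = ONE. A state is one such
# digit per TOG, encoded base 3 (TOG 1 least significant) as id 1..3^K.
# Per TOG the legal parent/child digit triples are:
#   parent ZERO    -> both children ZERO;
#   parent PENDING -> children anything except both ZERO;
#   parent ONE     -> children ZERO or ONE (a PENDING child would regain a
#                     lost gene, violating the intratree constraint).
# Across TOGs the union 1-set must stay connected, which locally means: a
# parent with some ONE digit may not have a child whose subtree holds
# detached 1s (child pending, i.e. no ONE digit but some PENDING digit),
# and a parent with no ONE digit may have 1s under at most one child.
node_centric_env <- new.env(parent = emptyenv())

nc_triples <- function(K) {
  key <- as.character(K)
  if (!is.null(node_centric_env[[key]])) return(node_centric_env[[key]])
  one_tog <- rbind(
    cbind(p = 0L, expand.grid(c1 = 0L, c2 = 0L)),
    cbind(p = 1L, expand.grid(c1 = 0:2, c2 = 0:2)[-1L, ]),   # not both ZERO
    cbind(p = 2L, expand.grid(c1 = c(0L, 2L), c2 = c(0L, 2L))))
  one_tog$w <- (one_tog$p == 2L) * ((one_tog$c1 != 2L) + (one_tog$c2 != 2L)) +
               (one_tog$p != 2L) * ((one_tog$c1 == 2L) + (one_tog$c2 == 2L))
  m <- nrow(one_tog)
  pick <- as.matrix(expand.grid(rep(list(seq_len(m)), K)))
  pw3 <- 3L^(seq_len(K) - 1L)
  pid <- 1L + as.vector((matrix(one_tog$p[pick], ncol = K) %*% pw3))
  c1id <- 1L + as.vector((matrix(one_tog$c1[pick], ncol = K) %*% pw3))
  c2id <- 1L + as.vector((matrix(one_tog$c2[pick], ncol = K) %*% pw3))
  w <- rowSums(matrix(one_tog$w[pick], ncol = K))
  # state statuses
  D <- as.matrix(expand.grid(rep(list(0:2), K)))   # digits of state id s
  has_one <- rowSums(D == 2L) > 0
  has_pend <- rowSums(D == 1L) > 0
  pending <- !has_one & has_pend
  active <- has_one | has_pend
  drop <- (has_one[pid] & (pending[c1id] | pending[c2id])) |
          (pending[pid] & active[c1id] & active[c2id])
  keep <- !drop
  tab <- list(pid = pid[keep], c1id = c1id[keep], c2id = c2id[keep],
              w = w[keep], n_states = 3L^K,
              digits = D, has_one = has_one)
  tab$by_p <- split(seq_along(tab$pid), tab$pid)
  node_centric_env[[key]] <- tab
  tab
}

#' Node-centric dynamic-programming solver
#'
#' Labels all K TOGs simultaneously by a post-order dynamic program over
#' per-node label vectors in \{0, 0-pending, 1\}^K, where "0-pending"
#' marks a node labeled 0 whose subtree still holds a 1 in that TOG. The
#' legal parent/child vector combinations encode the intratree constraint
#' per TOG and the intertree constraint through union connectivity (see
#' the source for the exact transition table); a pre-order backtrace
#' recovers one optimal labeling, with pending bookkeeping finalized to 0.
#'
#' @inheritParams label_exhaustive
#' @return A `tog_labeling` solution (see [label_exhaustive()]).
#' @export
label_node_centric <- function(problem) {
  tree <- problem$tree; K <- problem$K
  tab <- nc_triples(K)
  S <- tab$n_states
  pw3 <- 3L^(seq_len(K) - 1L)
  cost <- matrix(Inf, tree$n_nodes, S)
  choice <- matrix(NA_integer_, tree$n_nodes, S)
  for (v in seq_len(tree$n_nodes)) {
    if (tree$is_leaf[v]) {
      sid <- 1L + sum(2L * problem$labels[, v] * pw3)
      cost[v, sid] <- 0
    } else {
      ch <- tree$children[v, ]
      tot <- cost[ch[1L], tab$c1id] + cost[ch[2L], tab$c2id] + tab$w
      for (p in seq_len(S)) {
        idx <- tab$by_p[[as.character(p)]]
        if (is.null(idx)) next
        b <- idx[which.min(tot[idx])]
        cost[v, p] <- tot[b]
        choice[v, p] <- b
      }
    }
  }
  root_state <- which.min(cost[tree$root, ])   # lowest id on ties: prefers 0
  if (!is.finite(cost[tree$root, root_state]))
    stop("no feasible labeling (cannot occur when every TOG has a 1-leaf)")
  # pre-order backtrace; pending digits finalize to label 0
  state <- integer(tree$n_nodes)
  state[tree$root] <- root_state
  for (v in rev(seq_len(tree$n_nodes))) if (!tree$is_leaf[v]) {
    tr <- choice[v, state[v]]
    ch <- tree$children[v, ]
    state[ch[1L]] <- tab$c1id[tr]
    state[ch[2L]] <- tab$c2id[tr]
  }
  labels <- t((tab$digits[state, , drop = FALSE] == 2L) * 1)
  new_solution(labels, tree, "node")
}

## ----- tree-centric dynamic program -------------------------------------

#' Tree-centric dynamic-programming solver
#'
#' Processes the TOGs sequentially, maintaining for every reachable *union
#' TOG* (the node-wise Boolean OR of the labelings chosen so far) the
#' minimum accumulated flips. Each TOG contributes its intratree-feasible
#' labelings; the answer is the cheapest final union whose 1-set is
#' connected (the intertree constraint), and per-TOG labelings are
#' recovered by backtracing in reverse order. Guarded to trees with at
#' most 20 nodes (the union state space is 2^(2N-1)).
#'
#' @inheritParams label_exhaustive
#' @return A `tog_labeling` solution (see [label_exhaustive()]).
#' @export
label_tree_centric <- function(problem) {
  tree <- problem$tree; K <- problem$K
  if (tree$n_nodes > 20L)
    stop("species tree too large for the tree-centric solver (more than 20 nodes)")
  feas <- lapply(seq_len(K), function(k) enumerate_feasible(tree, problem$labels[k, ]))
  bits <- 2L^(seq_len(tree$n_nodes) - 1L)
  masks <- lapply(feas, function(f) as.integer(f$labels %*% bits))
  states <- 0L; costs <- 0
  bp <- vector("list", K)
  for (k in seq_len(K)) {
    nl <- length(masks[[k]]); ns <- length(states)
    # candidate (state, labeling) products; keep the cheapest per new union
    new <- bitwOr(rep(states, each = nl), rep(masks[[k]], times = ns))
    cand <- rep(costs, each = nl) + rep(feas[[k]]$flips, times = ns)
    ord <- order(cand, new)
    sel <- ord[!duplicated(new[ord])]
    bp[[k]] <- list(lab = ((sel - 1L) %% nl) + 1L,     # labeling row chosen
                    prev = ((sel - 1L) %/% nl) + 1L)   # state index before step
    states <- new[sel]; costs <- cand[sel]
  }
  # final answer: cheapest union whose 1-set is connected
  conn <- vapply(states, function(m) {
    ones <- bitwAnd(m, bits) > 0L
    ones_connected(ones, tree)
  }, logical(1L))
  if (!any(conn)) stop("no feasible labeling (cannot occur when every TOG has a 1-leaf)")
  cands <- which(conn & costs == min(costs[conn]))
  pick <- cands[order(states[cands])][1L]
  # backtrace
  labels <- matrix(NA_real_, K, tree$n_nodes)
  cur <- pick
  for (k in rev(seq_len(K))) {
    lab_idx <- bp[[k]]$lab[cur]
    labels[k, ] <- feas[[k]]$labels[lab_idx, ]
    cur <- bp[[k]]$prev[cur]
  }
  new_solution(labels, tree, "tree")
}

#' Solve a TOG labeling problem
#'
#' Dispatches to one of the three solvers. `auto` uses the node-centric
#' dynamic program when the number of TOGs is small relative to the number
#' of genomes (crossover heuristic `K <= N`) and the tree-centric program
#' otherwise.
#'
#' @inheritParams label_exhaustive
#' @param strategy One of `"auto"`, `"node"`, `"tree"`, `"exhaustive"`.
#' @return A `tog_labeling` solution (see [label_exhaustive()]).
#' @export
solve_labeling <- function(problem, strategy = c("auto", "node", "tree", "exhaustive")) {
  strategy <- match.arg(strategy)
  if (strategy == "auto")
    strategy <- if (problem$K <= problem$tree$n_leaves) "node" else "tree"
  switch(strategy,
         node = label_node_centric(problem),
         tree = label_tree_centric(problem),
         exhaustive = label_exhaustive(problem))
}
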