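#' Markov clustering of the similarity graph into gene families
#'
#' Reimplements the Markov Cluster algorithm on the weighted similarity
#' graph: the column-stochastic transition matrix (with self-loops of weight
#' equal to each vertex's maximum incident weight) is alternately expanded
#' (matrix squaring) and inflated (elementwise power followed by column
#' renormalization) until the matrix change drops below `tol` or `max_iter`
#' is reached. Clusters are read off the limit matrix from its attractors;
#' a gene attracted to several attractor sets is assigned to the one
#' receiving the larger flow mass, ties broken by lexicographically smallest
#' member gene id. Each connected component is clustered independently
#' (Markov clustering never joins disconnected components), so isolated
#' genes yield singleton families.
#'
#' @param graph A [similarity_graph()].
#' @param inflation Inflation exponent (> 1); default 2.
#' @param max_iter Maximum number of expansion/inflation rounds.
#' @param tol Convergence threshold on the max absolute matrix change.
#' @return A data frame with columns `family_id`, `gene_id`; family ids are
#'   `F0001`, `F0002`, ... ordered by each family's smallest gene id.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100L, tol = 1e-6) {
  stopifnot(inflation > 1)
  genes <- attr(graph, "genes")
  if (is.null(genes)) genes <- sort(unique(c(graph$gene_a, graph$gene_b)))
  if (!length(genes))
    return(data.frame(family_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    graph[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership[genes]
  lookup <- sim_lookup(graph)
  clusters <- list()
  for (cid in sort(unique(comp))) {
    members <- sort(genes[comp == cid])
    clusters <- c(clusters, mcl_component(members, graph, lookup,
                                          inflation, max_iter, tol))
  }
  clusters <- clusters[order(vapply(clusters, min, ""))]
  data.frame(
    family_id = rep(sprintf("F%04d", seq_along(clusters)), lengths(clusters)),
    gene_id = unlist(clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# cluster one connected component; returns list of character vectors
mcl_component <- function(members, graph, lookup, inflation, max_iter, tol) {
  m <- length(members)
  if (m == 1L) return(list(members))
  A <- matrix(0, m, m, dimnames = list(members, members))
  sub <- graph[graph$gene_a %in% members & graph$gene_b %in% members, , drop = FALSE]
  A[cbind(match(sub$gene_a, members), match(sub$gene_b, members))] <- sub$score
  A <- A + t(A)
  diag(A) <- apply(A, 1L, max)          # self-loop = max incident weight
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation
    M2[M2 < 1e-12] <- 0                 # prune for numerical stability
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Markov clustering did not converge within ", max_iter,
            " iterations; using current partition")
  mcl_interpret(M, members)
}

# read clusters off the (near-)limit matrix
mcl_interpret <- function(M, members) {
  thr <- 1e-6
  attractors <- which(diag(M) > thr)
  if (!length(attractors)) attractors <- unique(apply(M, 2L, which.max))
  # merge attractors that flow into each other
  ag <- igraph::graph_from_adjacency_matrix(M[attractors, attractors, drop = FALSE] > thr,
                                            mode = "max")
  amem <- igraph::components(ag)$membership
  n_cl <- max(amem)
  # assign every column to the attractor cluster receiving the most flow
  assign <- integer(length(members))
  for (j in seq_along(members)) {
    mass <- vapply(seq_len(n_cl), function(k)
      sum(M[attractors[amem == k], j]), numeric(1L))
    best <- which(mass == max(mass))
    if (length(best) > 1L) {   # tie: lexicographically smallest member id
      firsts <- vapply(best, function(k) min(members[attractors[amem == k]]), "")
      best <- best[order(firsts)][1L]
    }
    assign[j] <- best
  }
  unname(lapply(split(members, assign), sort))
}
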