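#' Build the padded multipartite graph of one gene family
#'
#' One stage per genome of the species tree holds that genome's family
#' members; all stages are padded with dummy vertices (`NA`) to the size of
#' the largest stage so that a perfect matching across stages exists.
#' Edges exist only between genes assigned as a pairwise ortholog pair, with
#' the pair's similarity bit score as weight; any other vertex pair
#' (including every pair involving a dummy) carries weight 0, which is
#' neutral for maximization and lets dummies absorb unmatched genes.
#'
#' @param family Character vector of the family's gene ids.
#' @param genes Data frame with columns `gene_id`, `genome`.
#' @param pairwise A `pairwise_orthologs` data frame
#'   (see [read_pairwise_orthologs()], [bbh_all_pairs()]). Pairs with an
#'   endpoint outside `family` are dropped.
#' @param tree The [species_tree()]; its leaves define the stages.
#' @return A `multipartite_graph`: list with `family` (sorted gene ids),
#'   `genomes`, `n_max`, `stages` (named list of length-`n_max` character
#'   vectors, `NA` = dummy) and `weights` (named score lookup).
#' @export
build_multipartite <- function(family, genes, pairwise, tree) {
  stopifnot(length(family) > 0L)
  family <- sort(unique(family))
  genomes <- sort(tree$labels[tree$is_leaf])
  gg <- genes[genes$gene_id %in% family, , drop = FALSE]
  unknown <- setdiff(gg$genome, genomes)
  if (length(unknown))
    stop("family contains genes from genome(s) not in the species tree: ",
         paste(unknown, collapse = ", "))
  stages <- lapply(genomes, function(g) sort(gg$gene_id[gg$genome == g]))
  names(stages) <- genomes
  n_max <- max(lengths(stages), 1L)
  stages <- lapply(stages, function(s) c(s, rep(NA_character_, n_max - length(s))))
  pw <- pairwise[pairwise$gene_a %in% family & pairwise$gene_b %in% family, , drop = FALSE]
  a <- pmin(pw$gene_a, pw$gene_b); b <- pmax(pw$gene_a, pw$gene_b)
  weights <- stats::setNames(pw$score, paste(a, b, sep = "\r"))
  structure(list(family = family, genomes = genomes, n_max = n_max,
                 stages = stages, weights = weights),
            class = "multipartite_graph")
}

#' Partition a gene family into super ortholog groups (SOGs)
#'
#' Heuristic maximum-weight multi-dimensional matching guided by the
#' species tree: each leaf starts with its genome's (padded) stage of
#' vertices; at every internal node, visited in post-order, the two child
#' stages of vertex tuples are merged by a maximum-weight bipartite
#' assignment ([hungarian_max()]) on the inter-stage weight matrix, so a
#' stage is always combined with a stage close to it on the species tree.
#' The weight between two tuples is the summed pairwise score of their
#' non-dummy members, which keeps total weight additive across merges.
#' After the root merge each tuple holding at least one gene becomes a SOG.
#'
#' @param graph A `multipartite_graph` from [build_multipartite()].
#' @param tree The [species_tree()] used to build it.
#' @return A list of class `sog_partition`: `sogs` is a list of named
#'   character vectors (genome -> gene id, at most one gene per genome),
#'   ordered by smallest member gene id; `total_weight` is the summed
#'   within-tuple score of the final matching.
#' @export
partition_family <- function(graph, tree) {
  genomes <- graph$genomes
  n_max <- graph$n_max
  w <- graph$weights
  tuple_w <- function(t1, t2) {
    if (!length(t1) || !length(t2)) return(0)
    k <- outer(t1, t2, function(x, y)
      paste(pmin(x, y), pmax(x, y), sep = "\r"))
    s <- w[as.vector(k)]
    sum(s[!is.na(s)])
  }
  stage_at <- vector("list", tree$n_nodes)
  for (v in seq_len(tree$n_nodes)) {
    if (tree$is_leaf[v]) {
      st <- graph$stages[[tree$labels[v]]]
      stage_at[[v]] <- lapply(seq_len(n_max), function(i) {
        if (is.na(st[i])) character(0L)
        else stats::setNames(st[i], tree$labels[v])
      })
    } else {
      s1 <- stage_at[[tree$children[v, 1L]]]
      s2 <- stage_at[[tree$children[v, 2L]]]
      W <- matrix(0, n_max, n_max)
      for (i in seq_len(n_max)) for (j in seq_len(n_max))
        W[i, j] <- tuple_w(s1[[i]], s2[[j]])
      asg <- hungarian_max(W)$assignment
      stage_at[[v]] <- lapply(seq_len(n_max), function(i) c(s1[[i]], s2[[asg[i]]]))
      stage_at[[tree$children[v, 1L]]] <- NULL_slot()
      stage_at[[tree$children[v, 2L]]] <- NULL_slot()
    }
  }
  tuples <- Filter(length, stage_at[[tree$root]])
  tuples <- lapply(tuples, function(t) t[order(names(t))])
  if (length(tuples))
    tuples <- tuples[order(vapply(tuples, min, ""))]
  total <- sum(vapply(tuples, function(t) {
    if (length(t) < 2L) return(0)
    s <- 0
    for (i in seq_len(length(t) - 1L)) for (j in (i + 1L):length(t))
      s <- s + tuple_w(t[i], t[j])
    s
  }, numeric(1L)))
  structure(list(sogs = tuples, total_weight = total), class = "sog_partition")
}

NULL_slot <- function() list()

#' Flatten SOG partitions of several families into a `sogs.tsv` data frame
#'
#' @param partitions Named list (by family id) of `sog_partition` objects.
#' @return Data frame with columns `sog_id`, `family_id`, `genome`,
#'   `gene_id`; SOG ids are `<family>.s<k>`.
#' @export
sogs_to_df <- function(partitions) {
  rows <- list()
  for (fam in names(partitions)) {
    sogs <- partitions[[fam]]$sogs
    for (k in seq_along(sogs)) {
      t <- sogs[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        sog_id = sprintf("%s.s%02d", fam, k), family_id = fam,
        genome = names(t), gene_id = unname(t), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sog_id = character(), family_id = character(),
                      genome = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
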