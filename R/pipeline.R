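#' Run the full ortholog-group inference pipeline
#'
#' Chains the five stages: (1) all-vs-all similarity scoring (unless a
#' precomputed [similarity_graph()] is supplied), (2) Markov clustering
#' into gene families, (3) pairwise one-to-one orthologs per genome pair
#' (bidirectional best hits within families, unless precomputed pairwise
#' assignments are supplied), (4) species-tree-guided multipartite matching
#' of every family into SOGs, and (5) minimum-flip TOG labeling followed by
#' ortholog-group extraction and event classification.
#'
#' @param genes Gene table (see [read_gene_table()]).
#' @param tree The [species_tree()].
#' @param sequences Named character vector of gene sequences (needed unless
#'   `similarity` is given).
#' @param similarity Optional precomputed [similarity_graph()].
#' @param orthologs Optional precomputed `pairwise_orthologs` (e.g. the
#'   output of a rearrangement-based pairwise tool read with
#'   [read_pairwise_orthologs()]); replaces the BBH stand-in.
#' @param min_score Similarity threshold passed to [score_all_pairs()].
#' @param inflation Markov-clustering inflation (see [mcl_cluster()]).
#' @param strategy Labeling solver selection (see [solve_labeling()]).
#' @return A `pipeline_result` list: `families`, `similarity`, `orthologs`,
#'   `sogs` (data frame), `groups` (data frame), `events` (data frame),
#'   `labelings` (named list of `tog_labeling` per family) and
#'   `total_flips`.
#' @export
run_pipeline <- function(genes, tree, sequences = NULL, similarity = NULL,
                         orthologs = NULL, min_score = 50, inflation = 2,
                         strategy = "auto") {
  tree <- species_tree(tree)
  if (is.null(similarity)) {
    if (is.null(sequences)) stop("either sequences or a similarity graph is required")
    similarity <- score_all_pairs(genes, sequences, min_score = min_score)
  }
  families <- mcl_cluster(similarity, inflation = inflation)
  families$genome <- genes$genome[match(families$gene_id, genes$gene_id)]
  if (is.null(orthologs))
    orthologs <- bbh_all_pairs(families, genes, similarity)
  # ortholog pairs must respect the family partition
  fam_of <- stats::setNames(families$family_id, families$gene_id)
  spanning <- fam_of[orthologs$gene_a] != fam_of[orthologs$gene_b]
  spanning[is.na(spanning)] <- TRUE
  if (any(spanning)) {
    warning(sum(spanning), " ortholog pair(s) span two families; dropped")
    orthologs <- orthologs[!spanning, , drop = FALSE]
  }
  fam_split <- split(families$gene_id, families$family_id)
  genomes <- tree$labels[tree$is_leaf]
  groups <- list(); events <- list(); labelings <- list(); parts <- list()
  for (fam in names(fam_split)) {
    part <- partition_family(
      build_multipartite(fam_split[[fam]], genes, orthologs, tree), tree)
    parts[[fam]] <- part
    sogs <- part$sogs
    if (!length(sogs)) next
    presence <- matrix(0, length(sogs), tree$n_leaves,
                       dimnames = list(NULL, genomes))
    for (k in seq_along(sogs)) presence[k, names(sogs[[k]])] <- 1
    sol <- solve_labeling(tog_problem(tree, presence), strategy = strategy)
    labelings[[fam]] <- sol
    for (k in seq_along(sogs)) {
      g <- extract_groups(sol$labels[k, ], tree, sogs[[k]],
                          family_id = fam, tog = k)
      if (nrow(g)) groups[[length(groups) + 1L]] <- g
    }
    ev <- classify_events(sol$labels, tree, family_id = fam)
    if (nrow(ev)) events[[length(events) + 1L]] <- ev
  }
  groups <- if (length(groups)) do.call(rbind, c(groups, list(make.row.names = FALSE)))
            else empty_groups()
  events <- if (length(events)) do.call(rbind, c(events, list(make.row.names = FALSE)))
            else empty_events()
  structure(list(families = families, similarity = similarity,
                 orthologs = orthologs, sogs = sogs_to_df(parts),
                 groups = groups, events = events, labelings = labelings,
                 total_flips = sum(vapply(labelings, `[[`, 0, "total_flips"))),
            class = "pipeline_result")
}

#' Simulate, run the pipeline and score it against the truth
#'
#' Convenience wrapper for closed-loop experiments: simulates one data set
#' with [evolve()], runs [run_pipeline()] on it, and evaluates the
#' predicted ortholog groups (exact match) and per-kind events against the
#' tracked truth.
#'
#' @param params A [sim_params()] object.
#' @param ... Passed on to [run_pipeline()].
#' @return List with `sim`, `result`, `group_metrics` ([score_groups()])
#'   and `event_metrics` ([score_events()]).
#' @export
simulate_and_score <- function(params, ...) {
  sim <- evolve(params)
  res <- run_pipeline(sim$genes, sim$tree, sequences = sim$sequences, ...)
  gm <- score_groups(res$groups, sim$truth$groups)
  em <- score_events(res$events, sim$truth$events)
  list(sim = sim, result = res, group_metrics = gm, event_metrics = em)
}
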