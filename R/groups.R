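#' Extract ortholog groups from one fully labeled TOG
#'
#' Anchors are the highest 1-labeled nodes of the TOG (nodes labeled 1
#' whose parent is labeled 0, plus the root when labeled 1). Each anchor
#' yields a candidate group: the SOG's genes at the 1-labeled leaves under
#' the anchor. Singleton groups (fewer than two genes) consist only of
#' lineage-specific copies and are discarded.
#'
#' @param labels Numeric 0/1 vector of length `n_nodes` (one labeled TOG).
#' @param tree The [species_tree()].
#' @param sog Named character vector genome -> gene id (the SOG behind the
#'   TOG).
#' @param family_id,tog Identifiers used to form deterministic group ids
#'   (`<family>.t<tog>.n<anchor>`).
#' @return Data frame with columns `group_id`, `genome`, `gene_id` (empty
#'   if no group with >= 2 genes exists).
#' @export
extract_groups <- function(labels, tree, sog, family_id = "F", tog = 1L) {
  if (anyNA(labels)) stop("labeling is incomplete (NA labels)")
  par_lab <- ifelse(is.na(tree$parent), 0, labels[tree$parent])
  anchors <- which(labels == 1 & par_lab == 0)
  rows <- list()
  for (a in anchors) {
    leaves <- st_descendant_leaves(tree, a)
    leaves <- leaves[labels[leaves] == 1]
    genomes <- tree$labels[leaves]
    members <- sog[genomes]
    members <- members[!is.na(members)]
    if (length(members) < 2L) next     # singleton rule
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = sprintf("%s.t%d.n%d", family_id, tog, a),
      genome = names(members), gene_id = unname(members),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_groups())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classify the evolutionary events of a family's labeled TOGs
#'
#' Every flip edge of every TOG becomes exactly one event: a 1->0
#' parent-child edge is a gene loss; a 0->1 edge is a gene birth if the
#' parent node is labeled 0 in *all other* TOGs of the family (the family
#' did not exist there yet), otherwise a gene duplication.
#'
#' @param labels K x `n_nodes` 0/1 matrix (the family's jointly labeled
#'   TOGs, intertree constraint satisfied).
#' @param tree The [species_tree()].
#' @param family_id Family identifier for the output rows.
#' @return Data frame with columns `family_id`, `tog`, `parent`, `child`,
#'   `event`; one row per flip edge.
#' @export
classify_events <- function(labels, tree, family_id = "F") {
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  if (anyNA(labels)) stop("labeling is incomplete (NA labels)")
  K <- nrow(labels)
  rows <- list()
  for (k in seq_len(K)) {
    for (v in which(!is.na(tree$parent))) {
      p <- tree$parent[v]
      lp <- labels[k, p]; lv <- labels[k, v]
      if (lp == lv) next
      if (lp == 1) kind <- "loss"
      else {
        others_zero <- K == 1L || all(labels[-k, p] == 0)
        kind <- if (others_zero) "birth" else "duplication"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = family_id, tog = k, parent = p, child = v,
        event = kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_events())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
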