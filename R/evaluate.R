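#' Exact-match scoring of predicted ortholog groups
#'
#' A predicted group is a true positive iff its gene set matches a known
#' (truth) group exactly. Sensitivity is TP divided by the number of known
#' groups; specificity is TP divided by the number of predicted groups
#' (elsewhere often called precision). An empty denominator yields `NA`
#' (undefined), never 0.
#'
#' @param predicted,truth Either data frames with a group id column
#'   (`group_id`) and a `gene_id` column, or lists of character vectors of
#'   gene ids.
#' @return List with `tp`, `n_truth`, `n_predicted`, `sensitivity`,
#'   `specificity`.
#' @export
score_groups <- function(predicted, truth) {
  pred <- as_group_sets(predicted)
  tru <- as_group_sets(truth)
  all_pred <- unlist(pred, use.names = FALSE)
  if (anyDuplicated(all_pred))
    stop("a gene occurs in more than one predicted group (partition violated)")
  pk <- vapply(pred, function(g) paste(sort(g), collapse = "\r"), "")
  tk <- vapply(tru, function(g) paste(sort(g), collapse = "\r"), "")
  tp <- length(intersect(pk, tk))
  list(tp = tp, n_truth = length(tk), n_predicted = length(pk),
       sensitivity = if (length(tk)) tp / length(tk) else NA_real_,
       specificity = if (length(pk)) tp / length(pk) else NA_real_)
}

as_group_sets <- function(x) {
  if (is.data.frame(x)) {
    id_col <- intersect(c("group_id", "lineage"), names(x))[1L]
    if (is.na(id_col) || !"gene_id" %in% names(x))
      stop("group data frame needs columns group_id (or lineage) and gene_id")
    x <- split(x$gene_id, x[[id_col]])
  }
  lapply(unname(x), unique)
}

#' Per-kind sensitivity/specificity of predicted evolutionary events
#'
#' Both sides are reduced to multisets of (species-tree branch, event kind)
#' pairs — the branch being the post-order index of the child node of the
#' edge — and compared by multiset intersection per kind. Gene identity is
#' not compared: an inferred loss carries no gene id, so the branch/kind
#' granularity is the finest level both sides share.
#'
#' @param predicted Data frame with columns `child` (or `branch`) and
#'   `event`.
#' @param truth Data frame with columns `branch` and `event`; `reversal`
#'   rows are ignored (reversals do not change gene content).
#' @return A data frame with one row per event kind: columns `event`,
#'   `tp`, `n_truth`, `n_predicted`, `sensitivity`, `specificity`.
#' @export
score_events <- function(predicted, truth) {
  br <- function(df) if ("branch" %in% names(df)) df$branch else df$child
  kinds <- c("birth", "duplication", "loss")
  pred <- data.frame(branch = br(predicted), event = predicted$event)
  tru <- truth[truth$event %in% kinds, c("branch", "event")]
  out <- lapply(kinds, function(k) {
    pt <- table(pred$branch[pred$event == k])
    tt <- table(tru$branch[tru$event == k])
    common <- intersect(names(pt), names(tt))
    tp <- sum(pmin(pt[common], tt[common]))
    np <- sum(pt); nt <- sum(tt)
    data.frame(event = k, tp = tp, n_truth = nt, n_predicted = np,
               sensitivity = if (nt) tp / nt else NA_real_,
               specificity = if (np) tp / np else NA_real_)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write evaluation metrics as JSON
#' @param metrics A list as produced by [score_groups()] (optionally with a
#'   `$events` element from [score_events()] and replicate aggregates).
#' @param path Output path (`metrics.json`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
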