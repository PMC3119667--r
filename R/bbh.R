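#' Bidirectional-best-hit pairwise orthologs within a family
#'
#' Stand-in for a rearrangement-based pairwise ortholog assignment tool when
#' its output is not available (e.g. on simulated data). Within one gene
#' family and one genome pair, genes whose best-scoring partners are mutual
#' (BBHs) are paired first; the remaining genes are then greedily paired in
#' order of descending similarity score to approximate one-to-one coverage.
#' All ties are broken lexicographically by gene id, and the result is
#' invariant under swapping the two genomes.
#'
#' Real runs can substitute files from a dedicated pairwise tool via
#' [read_pairwise_orthologs()]; the rest of the pipeline only consumes the
#' resulting pair set.
#'
#' @param family Character vector of the family's gene ids.
#' @param genes Data frame with columns `gene_id`, `genome`.
#' @param graph A [similarity_graph()] providing the scores.
#' @param genome_a,genome_b The two distinct genome ids.
#' @return A `pairwise_orthologs` data frame (columns `gene_a`, `genome_a`,
#'   `gene_b`, `genome_b`, `score`) with `genome_a < genome_b`.
#' @export
bbh_orthologs <- function(family, genes, graph, genome_a, genome_b) {
  stopifnot(genome_a != genome_b)
  if (genome_a > genome_b) { tmp <- genome_a; genome_a <- genome_b; genome_b <- tmp }
  ga <- sort(genes$gene_id[genes$genome == genome_a & genes$gene_id %in% family])
  gb <- sort(genes$gene_id[genes$genome == genome_b & genes$gene_id %in% family])
  empty <- validate_pairwise(data.frame(
    gene_a = character(), genome_a = character(), gene_b = character(),
    genome_b = character(), score = numeric(), stringsAsFactors = FALSE))
  if (!length(ga) || !length(gb)) return(empty)
  sub <- graph[(graph$gene_a %in% ga & graph$gene_b %in% gb) |
               (graph$gene_a %in% gb & graph$gene_b %in% ga), , drop = FALSE]
  if (!nrow(sub)) return(empty)
  # orient every edge as (a in genome_a, b in genome_b)
  swap <- sub$gene_a %in% gb
  ea <- ifelse(swap, sub$gene_b, sub$gene_a)
  eb <- ifelse(swap, sub$gene_a, sub$gene_b)
  edges <- data.frame(a = ea, b = eb, score = sub$score, stringsAsFactors = FALSE)
  edges <- edges[order(-edges$score, edges$a, edges$b), , drop = FALSE]
  best_of <- function(keys) {       # first (highest score, lex) partner per key
    !duplicated(keys)
  }
  best_a <- edges[best_of(edges$a), c("a", "b")]
  best_b <- edges[best_of(edges$b), c("a", "b")]
  bbh_key <- intersect(paste(best_a$a, best_a$b), paste(best_b$a, best_b$b))
  is_bbh <- paste(edges$a, edges$b) %in% bbh_key
  chosen <- edges[is_bbh & best_of(edges$a), , drop = FALSE]
  # greedy completion on the leftovers, descending score
  used_a <- chosen$a; used_b <- chosen$b
  rest <- edges[!(edges$a %in% used_a) & !(edges$b %in% used_b), , drop = FALSE]
  for (r in seq_len(nrow(rest))) {
    if (!(rest$a[r] %in% used_a) && !(rest$b[r] %in% used_b)) {
      chosen <- rbind(chosen, rest[r, , drop = FALSE])
      used_a <- c(used_a, rest$a[r]); used_b <- c(used_b, rest$b[r])
    }
  }
  validate_pairwise(data.frame(
    gene_a = chosen$a, genome_a = genome_a,
    gene_b = chosen$b, genome_b = genome_b,
    score = chosen$score, stringsAsFactors = FALSE))
}

#' Pairwise orthologs for all genome pairs of all families
#'
#' Applies [bbh_orthologs()] to every family and every unordered genome
#' pair and combines the results.
#'
#' @param families Data frame with columns `family_id`, `gene_id`.
#' @param genes Data frame with columns `gene_id`, `genome`.
#' @param graph A [similarity_graph()].
#' @return A `pairwise_orthologs` data frame over all genome pairs.
#' @export
bbh_all_pairs <- function(families, genes, graph) {
  genomes <- sort(unique(genes$genome))
  fam_split <- split(families$gene_id, families$family_id)
  out <- list()
  for (fam in fam_split) {
    fam_genomes <- sort(unique(genes$genome[genes$gene_id %in% fam]))
    if (length(fam_genomes) < 2L) next
    for (i in seq_len(length(fam_genomes) - 1L))
      for (j in (i + 1L):length(fam_genomes)) {
        p <- bbh_orthologs(fam, genes, graph, fam_genomes[i], fam_genomes[j])
        if (nrow(p)) out[[length(out) + 1L]] <- p
      }
  }
  df <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
        else data.frame(gene_a = character(), genome_a = character(),
                        gene_b = character(), genome_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  validate_pairwise(df)
}
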