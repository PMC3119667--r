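#' Build a similarity graph from an edge table
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `score`
#'   (positive weights; self-edges forbidden). Edges are stored with
#'   `gene_a < gene_b` so the graph is explicitly undirected.
#' @param genes Optional character vector of all vertex ids; defaults to the
#'   ids occurring in `edges`. Isolated genes matter for clustering
#'   (they form singleton families).
#' @return A `similarity_graph`: the canonicalized edge data frame with a
#'   `genes` attribute holding the vertex set.
#' @export
similarity_graph <- function(edges, genes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) stop("self-edges are not allowed")
  if (any(edges$score <= 0)) stop("similarity scores must be positive")
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  df <- data.frame(gene_a = a, gene_b = b, score = edges$score,
                   stringsAsFactors = FALSE)
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(genes)) genes <- sort(unique(c(df$gene_a, df$gene_b)))
  else genes <- sort(unique(c(genes, df$gene_a, df$gene_b)))
  attr(df, "genes") <- genes
  class(df) <- c("similarity_graph", "data.frame")
  df
}

#' Score all gene pairs by ungapped sequence identity
#'
#' Stand-in for an all-vs-all protein similarity search when working with
#' simulated genomes: every ordered pair of distinct genes receives the
#' bit-score-like value `2*matches - mismatches` of the ungapped end-to-end
#' comparison of their nucleotide sequences. The score is symmetric and
#' monotone in both alignment identity and length; identical sequences of
#' length L score 2L while unrelated random sequences (about 25% identity)
#' score negative and fall below any non-negative threshold. For real data
#' a precomputed `similarity.tsv` of e.g. BLASTp bit scores should be used
#' instead (see [read_similarity()]).
#'
#' Equal-length sequences (the simulator's output; substitutions preserve
#' length) are scored in one vectorized Hamming-distance pass. Pairs of
#' unequal length are scored from a global pairwise alignment
#' (match +2, mismatch -1, gap open/extend -4/-1).
#'
#' @param genes Data frame with at least `gene_id`; every gene must have a
#'   sequence.
#' @param sequences Named character vector of nucleotide sequences.
#' @param min_score Minimum score for an edge to be kept (default 50).
#' @return A [similarity_graph()] over all genes, containing the pairs with
#'   score `>= min_score` (and `> 0`).
#' @export
score_all_pairs <- function(genes, sequences, min_score = 50) {
  ids <- sort(genes$gene_id)
  missing <- setdiff(ids, names(sequences))
  if (length(missing))
    stop("missing sequence for gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  seqs <- sequences[ids]
  n <- length(ids)
  if (n < 2L)
    return(similarity_graph(data.frame(gene_a = character(), gene_b = character(),
                                       score = numeric()), genes = ids))
  lens <- nchar(seqs)
  edges <- list()
  if (length(unique(lens)) == 1L) {
    L <- lens[[1L]]
    d <- Biostrings::stringDist(Biostrings::DNAStringSet(seqs), method = "hamming")
    sc <- 2 * L - 3 * as.vector(d)       # = 2*matches - mismatches
    ij <- which_dist_pairs(n)
    keep <- sc >= min_score & sc > 0
    edges <- data.frame(gene_a = ids[ij$i[keep]], gene_b = ids[ij$j[keep]],
                        score = sc[keep], stringsAsFactors = FALSE)
  } else {
    # mixed lengths: Hamming within each length class, alignment across
    rows <- list()
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      if (lens[a] == lens[b]) {
        m <- sum(utf8ToInt(seqs[[a]]) == utf8ToInt(seqs[[b]]))
        sc <- 2 * m - (lens[a] - m)
      } else {
        al <- Biostrings::pairwiseAlignment(
          seqs[[a]], seqs[[b]], type = "global",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -1, baseOnly = FALSE),
          gapOpening = 4, gapExtension = 1)
        sc <- Biostrings::score(al)
      }
      if (sc >= min_score && sc > 0)
        rows[[length(rows) + 1L]] <- data.frame(gene_a = ids[a], gene_b = ids[b],
                                                score = sc, stringsAsFactors = FALSE)
    }
    edges <- if (length(rows)) do.call(rbind, rows)
             else data.frame(gene_a = character(), gene_b = character(), score = numeric())
  }
  similarity_graph(edges, genes = ids)
}

# row/col indices of the lower triangle in dist order (i > j per column j)
which_dist_pairs <- function(n) {
  j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- sequence((n - 1L):1L) + j
  list(i = i, j = j)   # note dist stores pairs (j, i) with j < i
}

# fast symmetric score lookup: returns named numeric environment-free helper
sim_lookup <- function(graph) {
  stats::setNames(graph$score, paste(graph$gene_a, graph$gene_b, sep = "\r"))
}

sim_get <- function(lookup, a, b, default = 0) {
  k <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- unname(lookup[k])
  out[is.na(out)] <- default
  out
}
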