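#' @title Tab-separated exchange formats
#' @description
#' All pipeline stages exchange small, diffable TSV files with fixed headers:
#' `genes.tsv` (gene_id, genome, chrom, position, strand),
#' `similarity.tsv` (gene_a, gene_b, score),
#' `orthologs.<G1>_<G2>.tsv` (gene_a, genome_a, gene_b, genome_b, score),
#' `families.tsv` (family_id, gene_id, genome),
#' `sogs.tsv` (sog_id, family_id, genome, gene_id),
#' `groups.tsv` (group_id, genome, gene_id) and
#' `events.tsv` (family_id, tog, parent, child, event).
#' Rows are written in a stable sort order so identical inputs produce
#' byte-identical files.
#' @name tsv-formats
NULL

read_tsv_checked <- function(path, cols) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ", paste(missing, collapse = ", "))
  df[, cols, drop = FALSE]
}

write_tsv_stable <- function(df, path) {
  if (nrow(df)) df <- df[do.call(order, df), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-genome gene table
#'
#' Expects columns `gene_id`, `genome`, `chrom`, `position`, `strand`.
#' Positions only need to be orderable within a chromosome: they are
#' rank-normalized to consecutive 0-based indices.
#'
#' @param path Path to `genes.tsv`.
#' @return A data frame with columns `gene_id`, `genome`, `chrom`,
#'   `position` (0-based rank within its chromosome) and `strand`
#'   (integer +1/-1), ordered by genome, chromosome and position.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "genome", "chrom", "position", "strand"))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df$position <- as.numeric(df$position)
  df$strand <- as.integer(df$strand)
  if (!all(df$strand %in% c(-1L, 1L))) stop("strand must be +1 or -1")
  normalize_gene_positions(df)
}

# rank-normalize positions to 0..len-1 per (genome, chrom)
normalize_gene_positions <- function(df) {
  key <- paste(df$genome, df$chrom, sep = "\r")
  for (k in unique(key)) {
    i <- which(key == k)
    if (anyDuplicated(df$position[i]))
      stop("duplicate position within genome/chromosome ", sub("\r", "/", k))
    df$position[i] <- rank(df$position[i]) - 1L
  }
  df$position <- as.integer(df$position)
  df[order(df$genome, df$chrom, df$position), , drop = FALSE]
}

#' Write a gene table
#' @param genes Data frame as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write_tsv_stable(genes[, c("gene_id", "genome", "chrom", "position", "strand")], path)
}

#' Read pairwise one-to-one ortholog assignments
#'
#' Each file holds the assignments for one genome pair with columns
#' `gene_a`, `genome_a`, `gene_b`, `genome_b`, `score`. Within a genome
#' pair every gene may occur at most once (the one-to-one constraint of a
#' pairwise ortholog assignment); violations are rejected.
#'
#' @param paths Character vector of `orthologs.<G1>_<G2>.tsv` paths.
#' @return A data frame (class `pairwise_orthologs`) with the five columns
#'   above, combined over all files.
#' @export
read_pairwise_orthologs <- function(paths) {
  parts <- lapply(paths, function(p)
    read_tsv_checked(p, c("gene_a", "genome_a", "gene_b", "genome_b", "score")))
  df <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(gene_a = character(), genome_a = character(),
                     gene_b = character(), genome_b = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  validate_pairwise(df)
}

validate_pairwise <- function(df) {
  if (nrow(df)) {
    if (any(df$genome_a == df$genome_b))
      stop("ortholog pair within a single genome is not allowed")
    # one-to-one per ordered genome pair, both sides
    ka <- paste(df$gene_a, df$genome_b, sep = "\r")
    kb <- paste(df$gene_b, df$genome_a, sep = "\r")
    if (anyDuplicated(ka) || anyDuplicated(kb)) {
      bad <- c(df$gene_a[duplicated(ka)], df$gene_b[duplicated(kb)])
      stop("gene(s) paired more than once against the same genome: ",
           paste(unique(bad), collapse = ", "))
    }
  }
  class(df) <- c("pairwise_orthologs", "data.frame")
  df
}

#' Write pairwise ortholog assignments, one file per genome pair
#' @param pairs A `pairwise_orthologs` data frame.
#' @param dir Output directory; files are named `orthologs.<G1>_<G2>.tsv`.
#' @return Character vector of file paths written, invisibly.
#' @export
write_pairwise_orthologs <- function(pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  key <- paste(pairs$genome_a, pairs$genome_b, sep = "_")
  paths <- character(0L)
  for (k in sort(unique(key))) {
    p <- file.path(dir, paste0("orthologs.", k, ".tsv"))
    write_tsv_stable(pairs[key == k, , drop = FALSE], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read/write a similarity table
#'
#' `similarity.tsv` holds the positive edge weights of the all-vs-all
#' similarity graph: columns `gene_a`, `gene_b`, `score`.
#'
#' @param path File path.
#' @param genes Optional character vector of all gene ids (vertices),
#'   including genes with no edge.
#' @return A `similarity_graph` (see [score_all_pairs()]).
#' @export
read_similarity <- function(path, genes = NULL) {
  df <- read_tsv_checked(path, c("gene_a", "gene_b", "score"))
  df$score <- as.numeric(df$score)
  similarity_graph(df, genes = genes)
}

#' @rdname read_similarity
#' @param graph A `similarity_graph`.
#' @export
write_similarity <- function(graph, path) {
  write_tsv_stable(as.data.frame(unclass(graph), stringsAsFactors = FALSE), path)
}

#' Read/write gene family assignments
#' @param path File path of `families.tsv`.
#' @return A data frame with columns `family_id`, `gene_id`, `genome`.
#' @export
read_families <- function(path) read_tsv_checked(path, c("family_id", "gene_id", "genome"))

#' @rdname read_families
#' @param families Data frame with columns `family_id`, `gene_id`, `genome`.
#' @export
write_families <- function(families, path) {
  write_tsv_stable(families[, c("family_id", "gene_id", "genome")], path)
}

#' Read/write super ortholog groups
#' @param path File path of `sogs.tsv`.
#' @return A data frame with columns `sog_id`, `family_id`, `genome`, `gene_id`.
#' @export
read_sogs <- function(path) read_tsv_checked(path, c("sog_id", "family_id", "genome", "gene_id"))

#' @rdname read_sogs
#' @param sogs Data frame with columns `sog_id`, `family_id`, `genome`, `gene_id`.
#' @export
write_sogs <- function(sogs, path) {
  write_tsv_stable(sogs[, c("sog_id", "family_id", "genome", "gene_id")], path)
}

#' Write final ortholog groups and evolutionary events
#'
#' @param groups Data frame with columns `group_id`, `genome`, `gene_id`.
#' @param events Data frame with columns `family_id`, `tog`, `parent`,
#'   `child` (species-tree post-order node indices) and `event` (one of
#'   `birth`, `duplication`, `loss`).
#' @param dir Output directory; writes `groups.tsv` and `events.tsv`.
#' @return Paths of the two files, invisibly.
#' @export
write_groups <- function(groups, events, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, "groups.tsv"); ep <- file.path(dir, "events.tsv")
  write_tsv_stable(groups[, c("group_id", "genome", "gene_id")], gp)
  write_tsv_stable(events[, c("family_id", "tog", "parent", "child", "event")], ep)
  invisible(c(gp, ep))
}

#' @rdname write_groups
#' @export
read_groups <- function(dir) {
  list(groups = read_tsv_checked(file.path(dir, "groups.tsv"),
                                 c("group_id", "genome", "gene_id")),
       events = read_tsv_checked(file.path(dir, "events.tsv"),
                                 c("family_id", "tog", "parent", "child", "event")))
}

#' Read/write gene sequences as FASTA
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_sequences
#' @param sequences Named character vector.
#' @export
write_sequences <- function(sequences, path) {
  sequences <- sequences[order(names(sequences))]
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path, width = 80L)
  invisible(path)
}

empty_events <- function() {
  data.frame(family_id = character(), tog = integer(), parent = integer(),
             child = integer(), event = character(), stringsAsFactors = FALSE)
}

empty_groups <- function() {
  data.frame(group_id = character(), genome = character(), gene_id = character(),
             stringsAsFactors = FALSE)
}
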