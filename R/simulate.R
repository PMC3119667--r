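#' Parameters of the genome-evolution simulator
#'
#' The simulator evolves single-chromosome genomes down a random species
#' tree. Along every branch it applies `events_per_branch` genome-level
#' events — gene duplications, gene births, gene losses and reversals in
#' the given proportions — interleaved with `events_per_branch + 1` equal
#' epochs of clock-like nucleotide substitution totalling
#' `mutation_branch_length` expected substitutions per site per branch.
#'
#' @param n_species Number of contemporary genomes (>= 2); default 5.
#' @param events_per_branch Evolutionary events per speciation branch;
#'   default 20.
#' @param mutation_branch_length Expected substitutions per site along one
#'   branch; default 0.02.
#' @param p_dup,p_birth,p_loss Fractions of events that are duplications,
#'   births and losses (defaults 0.4/0.2/0.2); the remainder are reversals.
#' @param tandem_fraction Fraction of duplications inserted immediately
#'   next to the source copy (default 0.5); the rest insert at a uniformly
#'   random position.
#' @param root_genes Genes in the root genome (default 100).
#' @param gene_length_nt Gene length in nucleotides, divisible by 3
#'   (default 3000).
#' @param seed Integer RNG seed; identical parameters and seed give
#'   byte-identical output.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_species = 5L, events_per_branch = 20L,
                       mutation_branch_length = 0.02,
                       p_dup = 0.4, p_birth = 0.2, p_loss = 0.2,
                       tandem_fraction = 0.5, root_genes = 100L,
                       gene_length_nt = 3000L, seed = 1L) {
  stopifnot(n_species >= 2L, events_per_branch >= 0L,
            mutation_branch_length >= 0,
            p_dup >= 0, p_birth >= 0, p_loss >= 0,
            p_dup + p_birth + p_loss <= 1 + 1e-12,
            tandem_fraction >= 0, tandem_fraction <= 1,
            root_genes >= 1L, gene_length_nt %% 3L == 0L)
  structure(list(n_species = as.integer(n_species),
                 events_per_branch = as.integer(events_per_branch),
                 mutation_branch_length = mutation_branch_length,
                 p_dup = p_dup, p_birth = p_birth, p_loss = p_loss,
                 tandem_fraction = tandem_fraction,
                 root_genes = as.integer(root_genes),
                 gene_length_nt = as.integer(gene_length_nt),
                 seed = as.integer(seed)), class = "sim_params")
}

#' Generate a random rooted binary species tree
#'
#' Builds the topology by sequential random leaf attachment: starting from
#' a two-leaf cherry, each further leaf is attached above a uniformly
#' chosen existing node (attachment above the root creates a new root).
#' Leaves are named `S1..Sn`.
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A [species_tree()].
#' @export
random_species_tree <- function(n_species, seed = NULL) {
  stopifnot(n_species >= 2L)
  if (!is.null(seed)) set.seed(seed)
  # nodes: 1..n_species leaves; internals appended as created
  left <- integer(0L); right <- integer(0L)   # children of internal node i (offset)
  n_int <- 0L
  parent <- rep(NA_integer_, n_species)
  int_id <- function(i) n_species + i
  root <- NA_integer_
  if (TRUE) {
    n_int <- 1L; left[1L] <- 1L; right[1L] <- 2L
    parent[1:2] <- int_id(1L); parent[int_id(1L)] <- NA_integer_
    root <- int_id(1L)
  }
  for (k in seq_len(n_species - 2L) + 2L) {
    nodes <- c(seq_len(k - 1L), int_id(seq_len(n_int)))
    v <- nodes[sample.int(length(nodes), 1L)]
    n_int <- n_int + 1L
    u <- int_id(n_int)
    p <- parent[v]
    left[n_int] <- v; right[n_int] <- k
    parent[u] <- p; parent[v] <- u; parent[k] <- u
    if (is.na(p)) root <- u
    else if (left[p - n_species] == v) left[p - n_species] <- u
    else right[p - n_species] <- u
  }
  nwk <- function(v) {
    if (v <= n_species) paste0("S", v)
    else paste0("(", nwk(left[v - n_species]), ",", nwk(right[v - n_species]), ")")
  }
  species_tree(paste0(nwk(root), ";"))
}

# nucleotide alphabet: 1=A 2=C 3=G 4=T; stop codons TAA TAG TGA
.nt <- c("A", "C", "G", "T")
.stop_codons <- c("TAA", "TAG", "TGA")

random_coding_sequence <- function(n_codons) {
  codons <- as.matrix(expand.grid(1:4, 1:4, 1:4))[, 3:1]
  lab <- apply(matrix(.nt[codons], ncol = 3L), 1L, paste, collapse = "")
  ok <- codons[!(lab %in% .stop_codons), , drop = FALSE]
  as.vector(t(ok[sample.int(nrow(ok), n_codons, replace = TRUE), , drop = FALSE]))
}

# Jukes-Cantor substitution over an epoch (int-vector sequence)
jc_mutate_int <- function(seq, epoch_length) {
  if (epoch_length <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * epoch_length / 3))
  hit <- which(stats::runif(length(seq)) < p)
  if (length(hit))
    seq[hit] <- ((seq[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  seq
}

#' Jukes-Cantor point mutation of gene sequences
#'
#' Independent-site nucleotide substitution: over an epoch of expected
#' length `epoch_length` substitutions per site, each site changes with the
#' closed-form Jukes-Cantor probability `3/4 * (1 - exp(-4*l/3))` to one of
#' the three other bases chosen uniformly. Sequence lengths are preserved.
#'
#' @param sequences Named character vector of A/C/G/T sequences.
#' @param epoch_length Expected substitutions per site (>= 0).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The mutated named character vector.
#' @export
mutate_sequences <- function(sequences, epoch_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(sequences, function(s) {
    v <- match(strsplit(s, "")[[1]], .nt)
    paste(.nt[jc_mutate_int(v, epoch_length)], collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' Simulate genome evolution with tracked ground truth
#'
#' Generates a random species tree, a root genome of `root_genes` random
#' coding-like genes, and evolves it along every branch (see
#' [sim_params()]). Lineage bookkeeping defines the true ortholog groups:
#' speciation copies a gene's lineage id into both daughter genomes, a
#' duplication gives the *new copy* a fresh lineage id (the original keeps
#' its id), and a birth starts a fresh lineage — so a lineage's leaf genes
#' are exactly the direct descendants of one ancestral gene, never
#' separated by a duplication. True groups are the lineages with at least
#' two leaf genes.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_result` list: `genes` (gene table, single chromosome
#'   `chr1` per genome), `sequences` (named character vector), `tree`
#'   (the [species_tree()]), `truth` with `groups` (columns `group_id`,
#'   `lineage`, `genome`, `gene_id`, only lineages with >= 2 leaf genes)
#'   and `events` (columns `branch` — the post-order index of the node a
#'   branch leads to — `event`, `lineage`), and `params`.
#' @export
evolve <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  tree <- random_species_tree(params$n_species)
  n_codons <- params$gene_length_nt %/% 3L
  lineage_counter <- params$root_genes
  root <- list(
    lineage = seq_len(params$root_genes),
    strand = sample(c(-1L, 1L), params$root_genes, replace = TRUE),
    seqs = replicate(params$root_genes, random_coding_sequence(n_codons),
                     simplify = FALSE))
  ev_rows <- list()
  leaf_genomes <- list()
  epoch <- if (params$events_per_branch >= 0L)
    params$mutation_branch_length / (params$events_per_branch + 1L)
  kinds <- c("duplication", "birth", "loss", "reversal")
  probs <- c(params$p_dup, params$p_birth, params$p_loss,
             max(0, 1 - params$p_dup - params$p_birth - params$p_loss))
  evolve_branch <- function(g, branch) {
    mut_all <- function(g) { g$seqs <- lapply(g$seqs, jc_mutate_int, epoch); g }
    g <- mut_all(g)
    for (e in seq_len(params$events_per_branch)) {
      kind <- sample(kinds, 1L, prob = probs)
      n <- length(g$lineage)
      if (kind == "duplication" && n > 0L) {
        src <- sample.int(n, 1L)
        lineage_counter <<- lineage_counter + 1L
        pos <- if (stats::runif(1L) < params$tandem_fraction) src + 1L
               else sample.int(n + 1L, 1L)
        g$lineage <- append(g$lineage, lineage_counter, after = pos - 1L)
        g$strand <- append(g$strand, g$strand[src], after = pos - 1L)
        g$seqs <- append(g$seqs, g$seqs[src], after = pos - 1L)
        ev_rows[[length(ev_rows) + 1L]] <<- data.frame(
          branch = branch, event = "duplication", lineage = lineage_counter)
      } else if (kind == "birth") {
        lineage_counter <<- lineage_counter + 1L
        pos <- sample.int(n + 1L, 1L)
        g$lineage <- append(g$lineage, lineage_counter, after = pos - 1L)
        g$strand <- append(g$strand, sample(c(-1L, 1L), 1L), after = pos - 1L)
        g$seqs <- append(g$seqs, list(random_coding_sequence(n_codons)), after = pos - 1L)
        ev_rows[[length(ev_rows) + 1L]] <<- data.frame(
          branch = branch, event = "birth", lineage = lineage_counter)
      } else if (kind == "loss") {
        if (n == 0L) { warning("gene loss on empty genome skipped"); next }
        i <- sample.int(n, 1L)
        ev_rows[[length(ev_rows) + 1L]] <<- data.frame(
          branch = branch, event = "loss", lineage = g$lineage[i])
        g$lineage <- g$lineage[-i]; g$strand <- g$strand[-i]; g$seqs <- g$seqs[-i]
      } else if (kind == "reversal") {
        if (n >= 2L) {
          ij <- sort(sample.int(n, 2L))
          r <- ij[1L]:ij[2L]
          g$lineage[r] <- rev(g$lineage[r])
          g$strand[r] <- -rev(g$strand[r])
          g$seqs[r] <- rev(g$seqs[r])
          ev_rows[[length(ev_rows) + 1L]] <<- data.frame(
            branch = branch, event = "reversal", lineage = NA_integer_)
        }
      }
      g <- mut_all(g)
    }
    g
  }
  walk <- function(node, g) {
    if (tree$is_leaf[node]) { leaf_genomes[[tree$labels[node]]] <<- g; return(invisible()) }
    for (ch in tree$children[node, ]) walk(ch, evolve_branch(g, ch))
  }
  walk(tree$root, root)
  # assemble outputs
  genes_rows <- list(); seqs <- character(0L); truth_rows <- list()
  for (gid in tree$labels[tree$is_leaf]) {
    g <- leaf_genomes[[gid]]
    n <- length(g$lineage)
    ids <- sprintf("%s_g%04d", gid, seq_len(n))
    genes_rows[[gid]] <- data.frame(
      gene_id = ids, genome = gid, chrom = "chr1",
      position = seq_len(n) - 1L, strand = g$strand, stringsAsFactors = FALSE)
    seqs <- c(seqs, stats::setNames(
      vapply(g$seqs, function(s) paste(.nt[s], collapse = ""), ""), ids))
    truth_rows[[gid]] <- data.frame(
      lineage = g$lineage, genome = gid, gene_id = ids, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, c(genes_rows, list(make.row.names = FALSE)))
  lin <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  keep <- lin$lineage %in% lin$lineage[duplicated(lin$lineage)]
  groups <- lin[keep, , drop = FALSE]
  groups <- groups[order(groups$lineage, groups$genome), , drop = FALSE]
  groups <- data.frame(group_id = sprintf("L%05d", groups$lineage), groups,
                       stringsAsFactors = FALSE, row.names = NULL)
  events <- if (length(ev_rows))
    do.call(rbind, c(ev_rows, list(make.row.names = FALSE)))
  else data.frame(branch = integer(), event = character(), lineage = integer())
  structure(list(genes = genes, sequences = seqs, tree = tree,
                 truth = list(groups = groups, events = events, lineages = lin),
                 params = params),
            class = "sim_result")
}

#' Write a simulation to the pipeline's file formats
#'
#' Writes `genes.tsv`, `genomes.fasta`, `species.nwk`, `truth_groups.tsv`
#' and `truth_events.tsv` into `dir`.
#'
#' @param sim A `sim_result` from [evolve()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_sequences(sim$sequences, file.path(dir, "genomes.fasta"))
  writeLines(sim$tree$newick, file.path(dir, "species.nwk"))
  write_tsv_stable(sim$truth$groups, file.path(dir, "truth_groups.tsv"))
  write_tsv_stable(sim$truth$events, file.path(dir, "truth_events.tsv"))
  invisible(dir)
}
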