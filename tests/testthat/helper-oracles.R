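# independent brute-force oracles and instance generators used across tests

# all permutations of 1..n as rows (n! x n)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    q <- p + (p >= k)
    cbind(rep(k, nrow(q)), q)
  }))
}

# exact assignment optimum by permutation enumeration
brute_assignment_max <- function(w) {
  n <- nrow(w)
  P <- all_perms(n)
  max(apply(P, 1L, function(p) sum(w[cbind(seq_len(n), p)])))
}

# random labeling instance on a random rooted binary tree
random_problem <- function(N, K) {
  tree <- random_species_tree(N)
  genomes <- tree$labels[tree$is_leaf]
  repeat {
    pres <- matrix(stats::rbinom(K * N, 1L, 0.5), K, N,
                   dimnames = list(NULL, genomes))
    if (all(rowSums(pres) > 0)) break
  }
  tog_problem(tree, pres)
}

# no optimal labeling may leave a 0 above two 1-children
lemma1_ok <- function(labels, tree) {
  for (k in seq_len(nrow(labels))) for (v in which(!tree$is_leaf)) {
    ch <- tree$children[v, ]
    if (labels[k, v] == 0 && all(labels[k, ch] == 1)) return(FALSE)
  }
  TRUE
}

# a 1 over two 0-children must be forced by the intertree constraint
lemma2_ok <- function(labels, tree) {
  for (k in seq_len(nrow(labels))) for (v in which(!tree$is_leaf)) {
    ch <- tree$children[v, ]
    if (labels[k, v] == 1 && all(labels[k, ch] == 0)) {
      relabeled <- labels
      relabeled[k, v] <- 0
      if (check_intertree(relabeled, tree)) return(FALSE)
    }
  }
  TRUE
}

# per-TOG minimum flips without the intertree constraint (independent DP-free
# reference: exhaustive per TOG, feasibility = intratree only)
unconstrained_min_flips <- function(problem) {
  sum(vapply(seq_len(problem$K), function(k) {
    single <- tog_problem(problem$tree,
                          matrix(problem$labels[k, which(problem$tree$is_leaf)],
                                 1L, dimnames = list(NULL,
                                   problem$tree$labels[problem$tree$is_leaf])))
    label_exhaustive(single, intertree = FALSE)$total_flips
  }, numeric(1L)))
}

# exact multipartite matching by enumerating stage alignments; stages is a
# list of per-genome padded vertex vectors (NA = dummy), wfun(a, b) a score
brute_multimatch <- function(stages, wfun) {
  n <- length(stages[[1L]])
  P <- all_perms(n)
  combos <- expand.grid(rep(list(seq_len(nrow(P))), length(stages) - 1L))
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    tuples <- lapply(seq_len(n), function(i) {
      v <- stages[[1L]][i]
      for (s in seq_along(stages)[-1L])
        v <- c(v, stages[[s]][P[combos[r, s - 1L], i]])
      v[!is.na(v)]
    })
    tot <- sum(vapply(tuples, function(t) {
      if (length(t) < 2L) return(0)
      s <- 0
      for (i in seq_len(length(t) - 1L)) for (j in (i + 1L):length(t))
        s <- s + wfun(t[i], t[j])
      s
    }, numeric(1L)))
    best <- max(best, tot)
  }
  best
}

# random one-to-one pairwise ortholog set over a toy family
random_toy_family <- function(genomes, sizes, seed_scores = NULL) {
  genes <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    if (sizes[i] == 0L) return(NULL)
    data.frame(gene_id = sprintf("%s_g%d", genomes[i], seq_len(sizes[i])),
               genome = genomes[i], chrom = "chr1",
               position = seq_len(sizes[i]) - 1L, strand = 1L,
               stringsAsFactors = FALSE)
  }))
  rows <- list()
  for (i in seq_len(length(genomes) - 1L)) for (j in (i + 1L):length(genomes)) {
    ga <- genes$gene_id[genes$genome == genomes[i]]
    gb <- genes$gene_id[genes$genome == genomes[j]]
    m <- min(length(ga), length(gb))
    if (m == 0L) next
    sel_a <- sample(ga, m); sel_b <- sample(gb, m)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = sel_a, genome_a = genomes[i], gene_b = sel_b,
      genome_b = genomes[j], score = round(stats::runif(m, 1, 100), 1),
      stringsAsFactors = FALSE)
  }
  pw <- if (length(rows)) do.call(rbind, rows)
        else data.frame(gene_a = character(), genome_a = character(),
                        gene_b = character(), genome_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  list(genes = genes, pairwise = pw)
}

# dense random multipartite instance: every cross-genome gene pair weighted
dense_random_stages <- function(genomes, sizes) {
  n_max <- max(sizes)
  stages <- lapply(seq_along(genomes), function(i) {
    s <- if (sizes[i]) sprintf("%s%d", genomes[i], seq_len(sizes[i])) else character(0L)
    c(s, rep(NA_character_, n_max - length(s)))
  })
  names(stages) <- genomes
  ids <- unlist(stages); ids <- ids[!is.na(ids)]
  pairs <- t(utils::combn(ids, 2L))
  same <- substr(pairs[, 1L], 1L, 2L) == substr(pairs[, 2L], 1L, 2L)
  pairs <- pairs[!same, , drop = FALSE]
  w <- stats::setNames(round(stats::runif(nrow(pairs), 0, 100), 2),
                       paste(pmin(pairs[, 1L], pairs[, 2L]),
                             pmax(pairs[, 1L], pairs[, 2L]), sep = "\r"))
  graph <- structure(list(family = sort(ids), genomes = genomes, n_max = n_max,
                          stages = stages, weights = w),
                     class = "multipartite_graph")
  wfun <- function(a, b) {
    x <- w[paste(pmin(a, b), pmax(a, b), sep = "\r")]
    if (is.na(x)) 0 else unname(x)
  }
  list(graph = graph, stages = stages, wfun = wfun)
}
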