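make_seqs <- function(n, L, seed = 1) {
  set.seed(seed)
  stats::setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""),
    sprintf("g%02d", seq_len(n)))
}

test_that("the similarity scorer is symmetric and separates related from random", {
  seqs <- make_seqs(4, 300)
  seqs[["g02"]] <- seqs[["g01"]]          # identical pair
  genes <- data.frame(gene_id = names(seqs),
                      genome = c("GA", "GB", "GA", "GB"), stringsAsFactors = FALSE)
  g <- score_all_pairs(genes, seqs, min_score = 1)
  key <- paste(g$gene_a, g$gene_b)
  # identical length-300 sequences score 2L and dominate that gene's edges
  expect_equal(g$score[key == "g01 g02"], 600)
  expect_true(all(g$score[key == "g01 g02"] >= g$score[g$gene_a == "g01" | g$gene_b == "g01"]))
  # i.i.d. random sequences fall below a stringent threshold: no edge
  expect_false(any(key %in% c("g03 g04", "g01 g03", "g01 g04", "g02 g03", "g02 g04")))
  # symmetry: scoring is invariant under listing order of the genes
  g_rev <- score_all_pairs(genes[rev(seq_len(nrow(genes))), ], seqs, min_score = 1)
  expect_equal(as.data.frame(g_rev), as.data.frame(g), ignore_attr = TRUE)
  expect_error(score_all_pairs(genes, seqs[-1L]), "missing sequence")
})

clique_edges <- function(members, weight) {
  do.call(rbind, lapply(seq_len(length(members) - 1L), function(i)
    data.frame(gene_a = members[i], gene_b = members[(i + 1L):length(members)],
               score = weight, stringsAsFactors = FALSE)))
}

test_that("Markov clustering recovers components, singletons and barbell splits", {
  # two disconnected cliques are two families at any inflation
  e <- rbind(clique_edges(c("a1", "a2", "a3"), 10),
             clique_edges(c("b1", "b2", "b3"), 10))
  for (infl in c(1.5, 2, 4)) {
    fams <- mcl_cluster(similarity_graph(e), inflation = infl)
    expect_equal(split(fams$gene_id, fams$family_id),
                 list(F0001 = c("a1", "a2", "a3"), F0002 = c("b1", "b2", "b3")),
                 ignore_attr = TRUE)
  }
  # five isolated genes -> five singleton families
  iso <- similarity_graph(data.frame(gene_a = character(), gene_b = character(),
                                     score = numeric()),
                          genes = sprintf("x%d", 1:5))
  fams <- mcl_cluster(iso)
  expect_equal(nrow(fams), 5L)
  expect_equal(length(unique(fams$family_id)), 5L)
  # barbell: two 4-cliques joined by one weak edge split at the weak edge
  barbell <- rbind(clique_edges(sprintf("L%d", 1:4), 10),
                   clique_edges(sprintf("R%d", 1:4), 10),
                   data.frame(gene_a = "L4", gene_b = "R1", score = 1))
  fams <- mcl_cluster(similarity_graph(barbell), inflation = 2)
  got <- unname(split(fams$gene_id, fams$family_id))
  expect_equal(length(got), 2L)
  expect_setequal(got[[1L]], sprintf("L%d", 1:4))
  expect_setequal(got[[2L]], sprintf("R%d", 1:4))
  # reference check: hand-rolled expansion/inflation iteration on the 8x8
  # matrix reaches the same two-block limit
  members <- sort(unique(c(barbell$gene_a, barbell$gene_b)))
  A <- matrix(0, 8, 8, dimnames = list(members, members))
  A[cbind(barbell$gene_a, barbell$gene_b)] <- barbell$score
  A <- A + t(A); diag(A) <- apply(A, 1, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (i in 1:50) { M <- M %*% M; M <- M^2; M <- sweep(M, 2, colSums(M), "/") }
  blocks <- unname(lapply(split(members, apply(M > 1e-6, 2, which.max)), sort))
  expect_setequal(lapply(got, sort), blocks)
})

test_that("families partition the gene set and refine connected components", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:12)
  e <- data.frame(gene_a = sample(genes, 20, replace = TRUE),
                  gene_b = sample(genes, 20, replace = TRUE),
                  score = round(stats::runif(20, 1, 50), 1))
  e <- e[e$gene_a != e$gene_b, ]
  g <- similarity_graph(e, genes = genes)
  fams <- mcl_cluster(g)
  expect_setequal(fams$gene_id, genes)                 # covers all genes
  expect_equal(anyDuplicated(fams$gene_id), 0L)        # disjoint
  # each family within one connected component
  ig <- igraph::graph_from_data_frame(g[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = genes))
  comp <- igraph::components(ig)$membership
  for (f in split(fams$gene_id, fams$family_id))
    expect_equal(length(unique(comp[f])), 1L)
  # permutation invariance: relabeling genes permutes the families
  perm <- stats::setNames(sprintf("h%02d", sample(12)), genes)
  g2 <- similarity_graph(data.frame(gene_a = unname(perm[e$gene_a]),
                                    gene_b = unname(perm[e$gene_b]),
                                    score = e$score),
                         genes = unname(perm))
  fams2 <- mcl_cluster(g2)
  orig <- lapply(split(fams$gene_id, fams$family_id), function(x) sort(unname(perm[x])))
  expect_setequal(unname(orig), unname(split(fams2$gene_id, fams2$family_id)))
})
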