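test_that("hungarian_max solves small assignments exactly", {
  h <- hungarian_max(rbind(c(5, 1), c(1, 5)))
  expect_equal(h$assignment, c(1L, 2L)); expect_equal(h$weight, 10)
  h <- hungarian_max(rbind(c(1, 2), c(3, 4)))
  expect_equal(h$assignment, c(2L, 1L)); expect_equal(h$weight, 5)
  expect_error(hungarian_max(matrix(1, 2, 3)), "square")
  expect_error(hungarian_max(rbind(c(1, Inf), c(0, 1))), "finite")
  set.seed(99)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    w <- matrix(round(stats::runif(n * n, -5, 10), 2), n, n)
    h <- hungarian_max(w)
    expect_equal(sort(h$assignment), seq_len(n))
    expect_equal(h$weight, brute_assignment_max(w))
  }
})

test_that("multipartite graphs are padded with dummies per stage", {
  tr <- species_tree("((GA,GB),GC);")
  genes <- data.frame(gene_id = c("a1", "a2", "b1"),
                      genome = c("GA", "GA", "GB"), stringsAsFactors = FALSE)
  pw <- data.frame(gene_a = "a1", genome_a = "GA", gene_b = "b1",
                   genome_b = "GB", score = 50, stringsAsFactors = FALSE)
  g <- build_multipartite(c("a1", "a2", "b1"), genes, pw, tr)
  expect_equal(g$n_max, 2L)
  expect_equal(lengths(g$stages), c(GA = 2L, GB = 2L, GC = 2L))
  expect_equal(sum(is.na(unlist(g$stages))), 3L)   # 0 + 1 + 2 dummies
  # no ortholog pairs at all -> edgeless padded graph still partitions
  g0 <- build_multipartite(c("a1", "a2"), genes, pw[0, ], tr)
  expect_equal(length(g0$weights), 0L)
  part <- partition_family(g0, tr)
  expect_equal(lengths(part$sogs), c(1L, 1L))      # two singleton SOGs
})

test_that("one gene per genome with complete edges yields a single full SOG", {
  tr <- species_tree("((GA,GB),(GC,GD));")
  genes <- data.frame(gene_id = sprintf("%s_1", c("GA", "GB", "GC", "GD")),
                      genome = c("GA", "GB", "GC", "GD"), stringsAsFactors = FALSE)
  cmb <- utils::combn(genes$gene_id, 2)
  pw <- data.frame(gene_a = cmb[1, ], genome_a = substr(cmb[1, ], 1, 2),
                   gene_b = cmb[2, ], genome_b = substr(cmb[2, ], 1, 2),
                   score = 10, stringsAsFactors = FALSE)
  part <- partition_family(build_multipartite(genes$gene_id, genes, pw, tr), tr)
  expect_equal(length(part$sogs), 1L)
  expect_setequal(unname(part$sogs[[1]]), genes$gene_id)
})

test_that("block-structured paralog weights split into the correct SOGs", {
  # 2 paralogs in each of 3 genomes; within-block score 100, cross-block 1:
  # exhaustive 3-dimensional matching picks the two blocks
  tr <- species_tree("((GA,GB),GC);")
  genomes <- c("GA", "GB", "GC")
  genes <- data.frame(gene_id = as.vector(outer(genomes, 1:2, paste0)),
                      genome = rep(genomes, 2), stringsAsFactors = FALSE)
  pw <- do.call(rbind, lapply(1:2, function(block_a) {
    do.call(rbind, lapply(1:2, function(block_b) {
      cmb <- utils::combn(genomes, 2)
      data.frame(gene_a = paste0(cmb[1, ], block_a), genome_a = cmb[1, ],
                 gene_b = paste0(cmb[2, ], block_b), genome_b = cmb[2, ],
                 score = if (block_a == block_b) 100 else 1,
                 stringsAsFactors = FALSE)
    }))
  }))
  # the one-to-one constraint forbids a gene holding both a within-block and
  # a cross-block partner in the same genome pair: keep the within-block set
  pw <- pw[pw$score == 100, ]
  part <- partition_family(build_multipartite(genes$gene_id, genes, pw, tr), tr)
  sets <- lapply(part$sogs, function(s) sort(unname(s)))
  expect_setequal(sets, list(c("GA1", "GB1", "GC1"), c("GA2", "GB2", "GC2")))
  # and the heuristic attains the brute-force 3-dimensional optimum here
  wfun <- function(a, b) {
    k <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    w <- stats::setNames(pw$score, paste(pmin(pw$gene_a, pw$gene_b),
                                         pmax(pw$gene_a, pw$gene_b), sep = "\r"))[k]
    if (is.na(w)) 0 else w
  }
  stages <- list(c("GA1", "GA2"), c("GB1", "GB2"), c("GC1", "GC2"))
  expect_equal(part$total_weight, brute_multimatch(stages, wfun))
})

test_that("SOG partitions satisfy their invariants on random families", {
  set.seed(11)
  tr <- species_tree("((GA,GB),(GC,GD));")
  for (rep in 1:25) {
    sizes <- sample(0:3, 4, replace = TRUE)
    if (sum(sizes) == 0) next
    toy <- random_toy_family(c("GA", "GB", "GC", "GD"), sizes)
    part <- partition_family(
      build_multipartite(toy$genes$gene_id, toy$genes, toy$pairwise, tr), tr)
    all_genes <- unlist(lapply(part$sogs, unname))
    expect_setequal(all_genes, toy$genes$gene_id)        # partition covers
    expect_equal(anyDuplicated(all_genes), 0L)           # and is disjoint
    for (s in part$sogs)
      expect_equal(anyDuplicated(names(s)), 0L)          # <=1 gene per genome
  }
})

test_that("the stage-merge heuristic is exact for singleton stages and near-optimal for small ones", {
  set.seed(21)
  genomes <- c("GA", "GB", "GC")
  tr <- species_tree("((GA,GB),GC);")
  # all stage sizes <= 1: heuristic weight equals the brute-force optimum
  for (rep in 1:20) {
    sizes <- sample(0:1, 3, replace = TRUE)
    if (sum(sizes) < 2) next
    toy <- random_toy_family(genomes, sizes)
    part <- partition_family(
      build_multipartite(toy$genes$gene_id, toy$genes, toy$pairwise, tr), tr)
    lk <- stats::setNames(toy$pairwise$score,
                          paste(pmin(toy$pairwise$gene_a, toy$pairwise$gene_b),
                                pmax(toy$pairwise$gene_a, toy$pairwise$gene_b), sep = "\r"))
    wfun <- function(a, b) {
      w <- lk[paste(pmin(a, b), pmax(a, b), sep = "\r")]
      if (is.na(w)) 0 else unname(w)
    }
    n_max <- max(sizes)
    stages <- lapply(genomes, function(g) {
      s <- toy$genes$gene_id[toy$genes$genome == g]
      c(s, rep(NA_character_, n_max - length(s)))
    })
    expect_equal(part$total_weight, brute_multimatch(stages, wfun))
  }
  # 3 stages of size <= 3 with dense random weights: aggregate regression
  # guard — the heuristic is not exact in general (single adversarial draws
  # can fall well below), but it must stay near the optimum on average
  ratios <- numeric(0)
  for (rep in 1:40) {
    d <- dense_random_stages(genomes, sample(1:3, 3, replace = TRUE))
    part <- partition_family(d$graph, tr)
    opt <- brute_multimatch(d$stages, d$wfun)
    if (opt > 0) ratios <- c(ratios, part$total_weight / opt)
  }
  expect_gte(mean(ratios), 0.9)
})
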