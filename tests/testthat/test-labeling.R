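quartet <- function() species_tree("((a,b),(c,d));")
pres <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("a", "b", "c", "d")
  m
}

test_that("count_flips counts bicolored edges", {
  tr <- quartet()
  expect_equal(count_flips(rep(1, 7), tr), 0)
  # root and left cherry 1, right subtree 0: single bicolored edge
  lab <- c(1, 1, 1, 0, 0, 0, 1)
  expect_equal(count_flips(lab, tr), 1)
  set.seed(3)
  for (i in 1:20) {
    lab <- stats::rbinom(7, 1, 0.5)
    manual <- sum(vapply(1:6, function(v) lab[v] != lab[tr$parent[v]], TRUE))
    expect_equal(count_flips(lab, tr), manual)
  }
  expect_error(count_flips(c(1, 1, NA, 0, 0, 0, 1), tr), "incomplete")
})

test_that("constraint checks match their definitions", {
  tr <- quartet()
  # loss then regain along a root path violates the intratree constraint
  lab <- c(1, 0, 0, 0, 0, 0, 1)     # leaf a = 1 under 0-labeled cherry, root 1
  expect_false(check_intratree(lab, tr))
  # a single 1-leaf satisfies both constraints
  lab <- c(1, 0, 0, 0, 0, 0, 0)
  expect_true(check_intratree(lab, tr))
  expect_true(check_intertree(lab, tr))
  # two 1-regions in different TOGs with a 0-root in both: path uncovered
  tog1 <- c(1, 0, 1, 0, 0, 0, 0)    # a + left internal
  tog2 <- c(0, 0, 0, 0, 1, 1, 0)    # d + right internal
  expect_true(check_intratree(tog1, tr) && check_intratree(tog2, tr))
  expect_false(check_intertree(rbind(tog1, tog2), tr))
})

test_that("the exhaustive oracle reproduces the worked micro-instances", {
  tr <- quartet()
  s <- label_exhaustive(tog_problem(tr, pres(c(1, 1, 1, 1))))
  expect_equal(s$total_flips, 0)
  expect_equal(unname(s$labels[1, ]), rep(1, 7))
  expect_equal(label_exhaustive(tog_problem(tr, pres(c(1, 1, 0, 0))))$total_flips, 1)
  p2 <- tog_problem(tr, pres(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  expect_equal(label_exhaustive(p2)$total_flips, 4)
  expect_equal(label_exhaustive(p2, intertree = FALSE)$total_flips, 2)
  expect_error(tog_problem(tr, pres(c(0, 0, 0, 0))), "all-zero")
  big <- species_tree(ape::write.tree(ape::stree(10, "left")))
  expect_error(label_exhaustive(tog_problem(big,
    matrix(1, 3, 10, dimnames = list(NULL, big$labels[big$is_leaf])))),
    "too large")
})

test_that("both dynamic programs agree with the oracle on the micro-instances", {
  tr <- quartet()
  for (solver in list(label_node_centric, label_tree_centric)) {
    expect_equal(solver(tog_problem(tr, pres(c(1, 1, 1, 1))))$total_flips, 0)
    expect_equal(solver(tog_problem(tr, pres(c(1, 1, 0, 0))))$total_flips, 1)
    expect_equal(solver(tog_problem(tr, pres(c(1, 0, 0, 0), c(0, 0, 0, 1))))$total_flips, 4)
  }
})

test_that("returned labelings satisfy constraints, lemmas and bounds on random instances", {
  set.seed(17)
  for (i in 1:40) {
    N <- sample(3:6, 1); K <- sample(1:3, 1)
    pr <- random_problem(N, K)
    sols <- list(label_exhaustive(pr), label_node_centric(pr), label_tree_centric(pr))
    flips <- vapply(sols, `[[`, 0, "total_flips")
    expect_true(all(flips == flips[1L]))
    for (s in sols) {
      for (k in seq_len(K)) expect_true(check_intratree(s$labels[k, ], pr$tree))
      expect_true(check_intertree(s$labels, pr$tree))
      expect_true(lemma1_ok(s$labels, pr$tree))
      expect_true(lemma2_ok(s$labels, pr$tree))
      expect_equal(count_flips(s$labels, pr$tree), s$total_flips)
    }
    # bounds: at most every edge flipped; at least one flip per mixed TOG
    leaf_cols <- which(pr$tree$is_leaf)
    mixed <- sum(apply(pr$labels[, leaf_cols, drop = FALSE], 1L,
                       function(x) any(x == 0) && any(x == 1)))
    expect_lte(flips[1L], K * (2 * N - 2))
    expect_gte(flips[1L], mixed)
    # the intertree constraint never decreases the optimum
    expect_gte(flips[1L], unconstrained_min_flips(pr))
  }
})

test_that("solver auto-selection follows the K <= N crossover and strategies agree", {
  tr <- species_tree(ape::write.tree(ape::stree(7, "left")))
  genomes <- tr$labels[tr$is_leaf]
  p_small <- tog_problem(tr, matrix(1, 1, 7, dimnames = list(NULL, genomes)))
  expect_equal(solve_labeling(p_small)$solver, "node")
  tr5 <- species_tree("((S1,S2),((S3,S4),S5));")
  set.seed(8)
  pres10 <- matrix(stats::rbinom(50, 1, 0.6), 10, 5,
                   dimnames = list(NULL, paste0("S", 1:5)))
  pres10[rowSums(pres10) == 0, 1] <- 1
  p_big <- tog_problem(tr5, pres10)
  expect_equal(solve_labeling(p_big)$solver, "tree")
  expect_equal(solve_labeling(p_big, "tree")$total_flips,
               label_tree_centric(p_big)$total_flips)
  p_mid <- tog_problem(tr5, pres10[1:3, ])
  expect_equal(solve_labeling(p_mid, "node")$total_flips,
               solve_labeling(p_mid, "tree")$total_flips)
})
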