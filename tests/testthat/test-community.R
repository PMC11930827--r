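two_triangles <- function(w = 1) {
  a <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- w
  }
  a
}

test_that("weighted graphs validate their invariants", {
  a <- two_triangles()
  g <- weighted_graph(a)
  expect_equal(g$m, 6)
  expect_equal(unname(g$k), rep(2, 6))
  expect_error(weighted_graph(a - 2), "negative")
  expect_error(weighted_graph(matrix(1:4, 2)), "symmetric")
})

test_that("positive subgraph drops and counts negative edges", {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["b", "c"] <- w["c", "b"] <- -0.2
  net <- list(w = w)
  g <- positive_subgraph(net)
  expect_equal(g$a["a", "b"], 0.5)
  expect_equal(g$a["b", "c"], 0)
  expect_equal(attr(g, "n_negative_dropped"), 1L)
  ## all-negative network: edgeless graph
  g2 <- positive_subgraph(list(w = -abs(two_triangles())))
  expect_equal(g2$m, 0)
  expect_equal(attr(g2, "n_negative_dropped"), 6L)
})

test_that("modularity evaluates the formula exactly", {
  a <- two_triangles()
  ## one community: exactly zero
  expect_equal(modularity_q(a, rep(1, 6)), 0)
  ## the planted triangles: 2 * (3/6 - (6/12)^2) = 0.5
  expect_equal(modularity_q(a, rep(1:2, each = 3)), 0.5)
  ## edgeless graph: defined as zero
  expect_equal(modularity_q(matrix(0, 3, 3), 1:3), 0)
  expect_error(modularity_q(a, 1:3), "labels")
})

test_that("modularity agrees with independent references on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(4:7, 1)
    a <- matrix(0, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (runif(1) < 0.6) a[i, j] <- a[j, i] <- round(runif(1, 0.1, 2), 2)
    }
    labels <- sample(1:3, p, replace = TRUE)
    expect_equal(modularity_q(a, labels), oracle_modularity(a, labels),
                 tolerance = 1e-10)
    if (sum(a) > 0) {
      g <- igraph::graph_from_adjacency_matrix(a, "undirected", weighted = TRUE)
      expect_equal(modularity_q(a, labels),
                   igraph::modularity(g, labels, weights = igraph::E(g)$weight),
                   tolerance = 1e-10)
    }
    ## resolution parameter against igraph's implementation
    expect_equal(modularity_q(a, labels, gamma_res = 1.7),
                 oracle_modularity(a, labels, gamma = 1.7), tolerance = 1e-10)
  }
})

test_that("fast-greedy recovers planted partitions and maximal Q on fixtures", {
  a <- two_triangles()
  part <- fast_greedy(a)
  expect_equal(part$q, 0.5, tolerance = 1e-12)
  expect_equal(unname(part$labels), rep(1:2, each = 3))
  ## matches exhaustive search over all 203 partitions of 6 nodes
  best <- oracle_best_partition(a)
  expect_equal(part$q, best$q, tolerance = 1e-12)

  gt <- make_planted_network(10, 3, w_in = 1, w_out = 0)
  part2 <- fast_greedy(weighted_graph(gt$w))
  expect_equal(unname(part2$labels), unname(gt$partition))
})

test_that("greedy modularity is bounded by the exhaustive optimum", {
  for (seed in 1:8) {
    set.seed(seed)
    p <- sample(5:8, 1)
    a <- matrix(0, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (runif(1) < 0.45) a[i, j] <- a[j, i] <- round(runif(1, 0.1, 1.5), 2)
    }
    if (sum(a) == 0) next
    part <- fast_greedy(a)
    best <- oracle_best_partition(a)
    expect_lte(part$q, best$q + 1e-10)
    ## returned Q is internally consistent with a from-scratch evaluation
    expect_equal(part$q, modularity_q(a, part$labels), tolerance = 1e-10)
  }
})

test_that("degenerate and isolated cases are handled deterministically", {
  ## single edge: Q = 0 both merged and split; earliest-max cut keeps singletons
  a <- matrix(c(0, 1, 1, 0), 2, dimnames = rep(list(c("a", "b")), 2))
  part <- fast_greedy(a)
  expect_equal(part$q, modularity_q(a, part$labels), tolerance = 1e-12)
  ## isolated nodes end as singletons
  a2 <- two_triangles()
  a3 <- rbind(cbind(a2, 0), 0)
  dimnames(a3) <- rep(list(letters[1:7]), 2)
  part3 <- fast_greedy(a3)
  expect_equal(sum(part3$labels == part3$labels[["g"]]), 1L)
  expect_equal(part3$q, 0.5, tolerance = 1e-12)
  ## edgeless graph: all singletons, Q = 0
  p0 <- fast_greedy(matrix(0, 3, 3))
  expect_equal(unname(p0$labels), 1:3)
  expect_equal(p0$q, 0)
  ## determinism
  expect_identical(fast_greedy(a2)$labels, fast_greedy(a2)$labels)
})

test_that("merge history is complete and Q-path consistent", {
  a <- two_triangles()
  part <- fast_greedy(a)
  expect_equal(nrow(part$merges), 5L)           # p - 1 merges recorded
  expect_equal(part$merges$q_after, part$q_path[-1], tolerance = 1e-12)
  expect_equal(max(part$q_path), part$q, tolerance = 1e-12)
})

test_that("the merge history serializes as a Newick-like dendrogram", {
  a <- two_triangles()
  part <- fast_greedy(a)
  nwk <- merge_newick(part)
  expect_match(nwk, ";$")
  for (nm in letters[1:6]) expect_match(nwk, nm)
  ## balanced parentheses
  expect_equal(lengths(regmatches(nwk, gregexpr("\\(", nwk))),
               lengths(regmatches(nwk, gregexpr("\\)", nwk))))
  ## with all merges recorded the full tree reaches a single root
  expect_equal(substr(nwk, 1, 1), "(")
})

test_that("raising the resolution never coarsens fixture partitions", {
  a <- two_triangles()
  a[3, 4] <- a[4, 3] <- 0.25    # weak bridge
  n_comms <- vapply(c(0.5, 1, 2, 4), function(g) {
    length(unique(fast_greedy(a, gamma_res = g)$labels))
  }, numeric(1))
  expect_true(all(diff(n_comms) >= 0))
})

test_that("igraph's fast-greedy agrees on the clean fixture", {
  a <- two_triangles()
  g <- igraph::graph_from_adjacency_matrix(a, "undirected", weighted = TRUE)
  ig <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  ours <- fast_greedy(a)
  expect_equal(igraph::modularity(ig), ours$q, tolerance = 1e-12)
  expect_equal(length(unique(igraph::membership(ig))),
               length(unique(ours$labels)))
})

test_that("planted communities are recovered from Gibbs-sampled data", {
  skip_if_not_installed("mclust")
  hits <- 0
  for (seed in 1:3) {
    gt <- make_planted_network(9, 3, w_in = 1.5, w_out = 0, b = 0)
    m <- gibbs_sample(gt, 10000, burn_in = 200, seed = seed)
    net <- fit_ising(m)
    part <- fast_greedy(positive_subgraph(net))
    ari <- mclust::adjustedRandIndex(part$labels, gt$partition)
    if (ari >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 2)
})
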