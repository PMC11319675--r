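two_triangles <- function() {
  list(nodes = letters[1:6],
       edges = data.frame(
         from = c("a", "b", "c", "d", "e", "f"),
         to = c("b", "c", "a", "e", "f", "d"),
         weight = 1, stringsAsFactors = FALSE))
}

test_that("Louvain recovers canonical small-graph optima", {
  p <- louvain_partition(two_triangles(), seed = 3)
  expect_equal(p$n_communities, 2)
  expect_equal(p$modularity, 0.5, tolerance = 1e-12)
  expect_equal(unname(p$membership[c("a", "b", "c")]),
               rep(p$membership[["a"]], 3))

  ## single edge: one community at Q = 0 (beats two singletons at -0.5)
  g1 <- list(nodes = c("x", "y"),
             edges = data.frame(from = "x", to = "y", weight = 1))
  p1 <- louvain_partition(g1, seed = 1)
  expect_equal(p1$n_communities, 1)
  expect_equal(p1$modularity, 0)
  expect_equal(modularity_q(g1, c(x = 1, y = 2)), -0.5)

  ## complete graph K4: one community
  g2 <- list(nodes = letters[1:4],
             edges = data.frame(from = c("a", "a", "a", "b", "b", "c"),
                                to = c("b", "c", "d", "c", "d", "d"),
                                weight = 1))
  expect_equal(louvain_partition(g2, seed = 5)$n_communities, 1)

  ## empty graph: empty partition
  g0 <- list(nodes = character(0),
             edges = data.frame(from = character(0), to = character(0),
                                weight = numeric(0)))
  expect_equal(louvain_partition(g0, seed = 1)$n_communities, 0)
})

test_that("reported modularity equals an independent recomputation (igraph)", {
  skip_if_not_installed("igraph")
  set.seed(14)
  for (rep in 1:10) {
    g <- make_two_block_graph(sample(5:8, 1), seed = 100 + rep)
    p <- louvain_partition(g, seed = rep)
    expect_equal(p$modularity, modularity_q(g, p$membership), tolerance = 1e-12)
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$nodes)
    q_ig <- igraph::modularity(ig, p$membership[igraph::V(ig)$name],
                               weights = igraph::E(ig)$weight)
    expect_equal(p$modularity, q_ig, tolerance = 1e-12)
  }
})

test_that("Louvain attains the exhaustive maximum on planted two-block graphs", {
  for (rep in 1:8) {
    g <- make_two_block_graph(sample(6:8, 1), seed = 200 + rep)
    p <- louvain_partition(g, seed = rep)
    ex <- exhaustive_max_modularity(g)
    expect_gte(p$modularity, ex$q_max - 1e-9)
    ## the planted blocks are the recovered communities
    expect_equal(adjusted_rand_index(p$membership[g$nodes], g$block[g$nodes]), 1)
  }
})

test_that("partitions are deterministic under a fixed seed and isolated nodes stay singletons", {
  g <- make_two_block_graph(8, seed = 33)
  g$nodes <- c(g$nodes, "iso1", "iso2")
  p1 <- louvain_partition(g, seed = 7)
  p2 <- louvain_partition(g, seed = 7)
  expect_identical(p1$membership, p2$membership)
  expect_false(p1$membership[["iso1"]] == p1$membership[["iso2"]])
  expect_false(any(p1$membership[["iso1"]] == p1$membership[g$nodes[1:8]]))
  ## self-loops and non-positive weights are rejected
  bad <- list(nodes = c("a", "b"),
              edges = data.frame(from = "a", to = "a", weight = 1))
  expect_error(louvain_partition(bad, seed = 1), "self-loops")
})

test_that("adjusted Rand index matches mclust on random labelings", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (rep in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2L, 3L, 4L, 5L, 6L)), 1)
})
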