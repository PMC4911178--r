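test_that("connectivity uses the inclusive 1 + R interaction radius", {
  pos <- rbind(c(0, 0), c(1.04, 0))
  expect_true(connectivity(pos, R = 0.05)[1, 2])
  expect_false(connectivity(rbind(c(0, 0), c(1.06, 0)), R = 0.05)[1, 2])
  # symmetric, no self-adjacency, for random input
  set.seed(21)
  p <- matrix(runif(60, 0, 5), ncol = 2)
  adj <- connectivity(p, 0.05)
  expect_identical(adj, t(adj))
  expect_false(any(diag(adj)))
  expect_error(connectivity(rbind(c(NA, 0))), "finite")
})

test_that("cluster identification matches independent component oracles", {
  # empty adjacency: all singletons
  a <- find_clusters(matrix(FALSE, 5, 5))
  expect_identical(a$sizes, rep(1L, 5))
  # chain 1-2, 2-3
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  expect_identical(find_clusters(adj)$sizes, 3L)
  # random geometric graphs against BFS and igraph
  set.seed(99)
  for (rep in 1:100) {
    g <- random_geometric_adjacency(50)
    ours <- find_clusters(g$adj)
    oracle <- bfs_components(g$adj)
    expect_identical(ours$labels, oracle)
    ig <- igraph::components(
      igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected"))
    canon <- function(labels) {
      gr <- unname(split(seq_along(labels), labels))
      gr[order(vapply(gr, min, integer(1)))]
    }
    expect_identical(canon(ours$labels), canon(as.integer(ig$membership)))
  }
})

test_that("cluster assignments always partition the nuclei", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_geometric_adjacency(sample(2:200, 1))
    a <- find_clusters(g$adj)
    expect_identical(sum(a$sizes), a$n_nuclei)
    expect_true(all(a$labels >= 1 & a$labels <= length(a$sizes)))
    expect_identical(tabulate(a$labels, length(a$sizes)), a$sizes)
  }
})

test_that("mass-weighted mean cluster size follows sum(sizes^2)/n", {
  singles <- find_clusters(matrix(FALSE, 4, 4))
  expect_identical(mean_cluster_size_per_nucleus(singles), 1)
  # one cluster of 4 plus two singletons: (16 + 1 + 1) / 6 = 3
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(10, 0), c(20, 0))
  a <- cluster_nuclei(pos, R = 0.05)
  expect_identical(mean_cluster_size_per_nucleus(a), 3)
  # a single cluster of n gives n
  chain <- cbind(seq(0, 6.3, by = 0.9), 0)
  expect_identical(mean_cluster_size_per_nucleus(cluster_nuclei(chain)),
                   nrow(chain) * 1)
  expect_error(mean_cluster_size_per_nucleus(find_clusters(matrix(FALSE, 0, 0))),
               "empty")
})

test_that("mass-weighted mean dominates the unweighted mean (Cauchy-Schwarz)", {
  set.seed(31)
  for (rep in 1:50) {
    g <- random_geometric_adjacency(sample(5:80, 1))
    a <- find_clusters(g$adj)
    mw <- mean_cluster_size_per_nucleus(a)
    uw <- mean_cluster_size(a)
    expect_gte(mw, uw - 1e-12)
    if (length(unique(a$sizes)) == 1) expect_equal(mw, uw)
  }
})

test_that("cluster census honours the size floor", {
  pos <- rbind(cbind(seq(0, 6, by = 1), 0),      # chain of 7
               cbind(seq(20, 22, by = 1), 5),    # chain of 3
               c(40, 0))                         # singleton
  a <- cluster_nuclei(pos)
  expect_identical(sort(a$sizes, decreasing = TRUE), c(7L, 3L, 1L))
  expect_identical(cluster_census(a, min_size = 7), 1L)
  expect_identical(cluster_census(a, min_size = 2), 2L)
  expect_identical(cluster_census(find_clusters(matrix(FALSE, 0, 0)), 2), 0L)
})
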