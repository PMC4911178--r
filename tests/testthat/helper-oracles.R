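# Independent oracles used across the suite.

# brute-force connected components by breadth-first search on an adjacency
# matrix; returns canonical labels (first-seen order), like find_clusters
bfs_components <- function(adj) {
  n <- nrow(adj)
  labels <- integer(n)
  ncl <- 0L
  for (root in seq_len(n)) {
    if (labels[root] != 0L) next
    ncl <- ncl + 1L
    queue <- root
    labels[root] <- ncl
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- ncl
      queue <- c(queue, nb)
    }
  }
  labels
}

# random geometric graph: n points in a box, edges within radius
random_geometric_adjacency <- function(n, box = 10, radius = 1.05) {
  pts <- cbind(runif(n, 0, box), runif(n, 0, box))
  d <- as.matrix(dist(pts))
  adj <- d <= radius
  diag(adj) <- FALSE
  list(positions = pts, adj = adj)
}

# exhaustive all-pairs nearest-neighbour edge distances
nn_edge_oracle <- function(x, y, r) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) - r[i] - r[j]
      best <- min(best, max(d, 0))
    }
    out[i] <- best
  }
  out
}

# Wald-Wolfowitz runs test p-value for independence of a numeric sequence
# (signs relative to the median)
runs_test_p <- function(x) {
  s <- sign(x - median(x))
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(1)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

# small-domain parameters shared by the quicker dynamical tests
small_params <- function(...) {
  sim_params(n_nuclei = 30, length = 55, t_end = 5, ...)
}
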