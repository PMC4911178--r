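#' Interaction adjacency of a nuclear configuration
#'
#' Two nuclei are connected when their centre-to-centre distance is at most
#' `1 + R`, i.e. when they lie within the radius of interaction of the
#' adhesive shell. Returns the full logical adjacency matrix (no
#' self-adjacency), mirroring the connectivity matrix formed at the end of a
#' simulation run.
#'
#' @param positions n x 2 matrix of centres, nuclear diameters.
#' @param R Shell width beyond contact (default 0.05).
#' @return n x n logical matrix, symmetric with a `FALSE` diagonal.
#' @export
connectivity <- function(positions, R = 0.05) {
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("positions must be finite")
  n <- nrow(positions)
  if (n == 0) return(matrix(FALSE, 0, 0))
  d <- as.matrix(dist(positions))
  adj <- d <= 1 + R
  diag(adj) <- FALSE
  adj
}

#' Connected clusters of the interaction graph
#'
#' Identifies the clusters as the connected components of the undirected
#' interaction graph, using an iterative Tarjan-style depth-first search
#' with an explicit stack (no recursion-depth limit, so graphs of 1e4+
#' nodes are fine).
#'
#' @param adjacency Logical adjacency matrix (as from [connectivity()]) or a
#'   list of integer neighbour vectors.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (cluster index per nucleus, numbered in order of discovery), `sizes`
#'   (count per cluster) and `n_nuclei`.
#' @examples
#' adj <- matrix(FALSE, 3, 3); adj[1, 2] <- adj[2, 1] <- TRUE
#' find_clusters(adj)$sizes   # 2, 1
#' @export
find_clusters <- function(adjacency) {
  if (is.matrix(adjacency)) {
    n <- nrow(adjacency)
    nbrs <- lapply(seq_len(n), function(i) which(adjacency[i, ]))
  } else if (is.list(adjacency)) {
    n <- length(adjacency)
    nbrs <- adjacency
  } else stop("adjacency must be a logical matrix or neighbour list")

  labels <- integer(n)
  ncl <- 0L
  for (root in seq_len(n)) {
    if (labels[root] != 0L) next
    ncl <- ncl + 1L
    stack <- root
    labels[root] <- ncl
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in nbrs[[v]]) {
        if (labels[w] == 0L) {
          labels[w] <- ncl
          stack <- c(stack, w)
        }
      }
    }
  }
  sizes <- if (ncl > 0) tabulate(labels, nbins = ncl) else integer(0)
  structure(list(labels = labels, sizes = sizes, n_nuclei = n),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", x$n_nuclei, "nuclei in", length(x$sizes),
      "clusters")
  if (x$n_nuclei > 0)
    cat(" (largest:", max(x$sizes), ")")
  cat("\n")
  invisible(x)
}

#' Cluster nuclei directly from positions
#'
#' Convenience wrapper: [connectivity()] followed by [find_clusters()].
#'
#' @inheritParams connectivity
#' @return A `cluster_assignment`.
#' @export
cluster_nuclei <- function(positions, R = 0.05) {
  find_clusters(connectivity(positions, R))
}

#' Mass-weighted mean cluster size
#'
#' The average size of the cluster of which a uniformly chosen nucleus is a
#' member: `sum(sizes^2) / n_nuclei`, with singletons counted as clusters of
#' size 1. This nucleus-weighted mean is the sweep summary metric; it is
#' always at least the unweighted mean cluster size (Cauchy-Schwarz), with
#' equality only when all clusters are equal-sized.
#'
#' @param assignment A `cluster_assignment`.
#' @return Scalar in `[1, n_nuclei]`.
#' @examples
#' a <- find_clusters(connectivity(cbind(c(0, 1, 2, 10, 20, 30), 0)))
#' mean_cluster_size_per_nucleus(a)  # (9 + 1 + 1 + 1) / 6 = 2
#' @export
mean_cluster_size_per_nucleus <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (assignment$n_nuclei < 1)
    stop("mean cluster size is undefined for an empty assignment")
  sum(assignment$sizes^2) / assignment$n_nuclei
}

#' Unweighted mean cluster size
#'
#' @param assignment A `cluster_assignment`.
#' @return Mean of the cluster sizes (singletons included).
#' @export
mean_cluster_size <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (assignment$n_nuclei < 1)
    stop("mean cluster size is undefined for an empty assignment")
  mean(assignment$sizes)
}

#' Census of clusters at a size floor
#'
#' Number of clusters with at least `min_size` members. The model's cluster
#' census uses `min_size = 2` (two or more adhered nuclei form a cluster);
#' the time-trend census of clusters with more than six nuclei uses
#' `min_size = 7`.
#'
#' @param assignment A `cluster_assignment`.
#' @param min_size Size floor (`>= 1`).
#' @return Integer count.
#' @export
cluster_census <- function(assignment, min_size = 2) {
  stopifnot(inherits(assignment, "cluster_assignment"), min_size >= 1)
  sum(assignment$sizes >= min_size)
}

#' Export a cluster assignment as a table
#'
#' @param assignment A `cluster_assignment`.
#' @param path Optional CSV path; when `NULL` the data frame is returned
#'   only.
#' @return Data frame with columns `nucleus_id`, `cluster_id`,
#'   `cluster_size`.
#' @export
cluster_table <- function(assignment, path = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  df <- data.frame(nucleus_id = seq_len(assignment$n_nuclei),
                   cluster_id = assignment$labels,
                   cluster_size = assignment$sizes[assignment$labels])
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
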