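#' Synthetic pattern generator specification
#'
#' Parameters of the ground-truthed generators that emulate the measured
#' structures: clustered vs dispersed nuclear point patterns (SNC/SNA-like
#' groups on a quiet background), cell populations mixing mononucleate cells
#' with multinucleate syncytia, and right-skewed shed-particle area
#' distributions. Defaults mirror the observed scales: 2.5 um nuclear
#' radius, ~0.8 um intra-cluster edge gaps (the median internuclear distance
#' inside syncytia), cluster hull areas of a few hundred um^2, and lognormal
#' particle areas spanning the 80-900 um^2 range.
#'
#' @param n_clusters Number of planted clusters.
#' @param cluster_sizes Either a single size applied to all clusters, a
#'   vector of per-cluster sizes, or `"poisson"` for shifted-Poisson sizes
#'   (`min_cluster_size + rpois(lambda)`).
#' @param poisson_lambda,min_cluster_size Parameters of the `"poisson"`
#'   option.
#' @param intra_cluster_gap Edge-to-edge gap between adjacent members, um.
#' @param inter_cluster_spacing Minimum spacing between cluster seed
#'   centres, um.
#' @param background_nuclei Count of dispersed background nuclei.
#' @param nucleus_radius Nuclear radius, um.
#' @param field Field rectangle `c(width, height)`, um.
#' @param particle_meanlog,particle_sdlog Lognormal parameters of the
#'   particle-area generator (um^2 scale).
#' @param jitter_sd Optional positional noise SD (um) for the robustness
#'   mode; the default 0 keeps placement deterministic so recovery tests are
#'   exact.
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_clusters = 3, cluster_sizes = 8,
                           poisson_lambda = 4, min_cluster_size = 6,
                           intra_cluster_gap = 0.8,
                           inter_cluster_spacing = 60,
                           background_nuclei = 20,
                           nucleus_radius = 2.5,
                           field = c(400, 400),
                           particle_meanlog = log(150),
                           particle_sdlog = 0.9,
                           jitter_sd = 0, seed = NULL) {
  stopifnot(n_clusters >= 0, intra_cluster_gap > 0,
            inter_cluster_spacing > 0, background_nuclei >= 0,
            nucleus_radius > 0, length(field) == 2, all(field > 0),
            particle_sdlog >= 0, jitter_sd >= 0)
  structure(list(n_clusters = n_clusters, cluster_sizes = cluster_sizes,
                 poisson_lambda = poisson_lambda,
                 min_cluster_size = min_cluster_size,
                 intra_cluster_gap = intra_cluster_gap,
                 inter_cluster_spacing = inter_cluster_spacing,
                 background_nuclei = background_nuclei,
                 nucleus_radius = nucleus_radius, field = field,
                 particle_meanlog = particle_meanlog,
                 particle_sdlog = particle_sdlog,
                 jitter_sd = jitter_sd, seed = seed),
            class = "generator_spec")
}

# hexagonal-lattice offsets around the origin with centre spacing `a`,
# enumerated centre-first then ring by ring
hex_offsets <- function(k, a) {
  if (k <= 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(c(0, 0), 1, 2)
  ring <- 1L
  dirs <- rbind(c(1, 0), c(0.5, sqrt(3) / 2), c(-0.5, sqrt(3) / 2),
                c(-1, 0), c(-0.5, -sqrt(3) / 2), c(0.5, -sqrt(3) / 2))
  while (nrow(pts) < k) {
    p <- ring * dirs[5, ]  # start corner of the ring
    for (side in 1:6) {
      step <- dirs[side, ]
      for (s in seq_len(ring)) {
        p <- p + step
        pts <- rbind(pts, p)
        if (nrow(pts) >= k) break
      }
      if (nrow(pts) >= k) break
    }
    ring <- ring + 1L
  }
  pts[seq_len(k), , drop = FALSE] * a
}

#' Generate a clustered nuclear point pattern with ground truth
#'
#' Plants `n_clusters` compact hexagonal-packed clusters (adjacent members
#' at edge-to-edge gap `intra_cluster_gap`) with seed centres at least
#' `inter_cluster_spacing` apart, plus uniform background nuclei kept at
#' least twice the SNC gap threshold away from every cluster nucleus and
#' from each other. Placement is deterministic given the seed, so planted
#' membership can be recovered exactly by the cluster-call operations.
#'
#' @param spec A [generator_spec()].
#' @param snc_gap The detection threshold the background keeps clear of
#'   (default 3 um).
#' @return A [point_pattern()] with attribute `truth`: a list with
#'   `labels` (planted cluster index per nucleus, 0 = background),
#'   `n_clusters` and `cluster_sizes`.
#' @export
generate_clustered_pattern <- function(spec = generator_spec(), snc_gap = 3) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  r <- spec$nucleus_radius
  a <- 2 * r + spec$intra_cluster_gap       # centre spacing inside clusters
  sizes <- cluster_size_draws(spec)
  W <- spec$field[1]; H <- spec$field[2]

  # cluster extent: outermost hex ring radius plus nucleus radius
  margin <- if (length(sizes)) max(vapply(sizes, function(k) {
    off <- hex_offsets(k, a)
    max(sqrt(rowSums(off^2))) + r
  }, numeric(1))) else 0
  margin <- margin + snc_gap

  if (spec$n_clusters > 0 && (2 * margin >= W || 2 * margin >= H))
    stop("field too small for the cluster extent plus clearance margin")
  seeds <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(seeds) < spec$n_clusters) {
    if (attempts > 5000L)
      stop(sprintf(paste0("could not place %d cluster seeds >= %g um apart ",
                          "in a %g x %g field (placed %d); enlarge the field ",
                          "or reduce spacing"),
                   spec$n_clusters, spec$inter_cluster_spacing, W, H,
                   nrow(seeds)))
    attempts <- attempts + 1L
    cand <- c(runif(1, margin, W - margin), runif(1, margin, H - margin))
    ok <- nrow(seeds) == 0 ||
      min(sqrt((seeds[, 1] - cand[1])^2 + (seeds[, 2] - cand[2])^2)) >=
        spec$inter_cluster_spacing
    if (ok) seeds <- rbind(seeds, cand)
  }

  xs <- numeric(0); ys <- numeric(0); labs <- integer(0)
  for (ci in seq_along(sizes)) {
    off <- hex_offsets(sizes[ci], a)
    if (spec$jitter_sd > 0)
      off <- off + matrix(rnorm(length(off), 0, spec$jitter_sd), ncol = 2)
    xs <- c(xs, seeds[ci, 1] + off[, 1])
    ys <- c(ys, seeds[ci, 2] + off[, 2])
    labs <- c(labs, rep(ci, sizes[ci]))
  }

  # dispersed background, clear of clusters and of each other
  clearance <- 2 * snc_gap + 2 * r
  bg_placed <- 0L
  attempts <- 0L
  while (bg_placed < spec$background_nuclei) {
    if (attempts > 20000L)
      stop("could not place the requested background nuclei; field too full")
    attempts <- attempts + 1L
    cx <- runif(1, r, W - r); cy <- runif(1, r, H - r)
    if (length(xs) && min(sqrt((xs - cx)^2 + (ys - cy)^2)) < clearance) next
    xs <- c(xs, cx); ys <- c(ys, cy); labs <- c(labs, 0L)
    bg_placed <- bg_placed + 1L
  }

  pat <- point_pattern(xs, ys, radius = r,
                       field_area_mm2 = W * H / 1e6)
  attr(pat, "truth") <- list(labels = labs,
                             n_clusters = length(sizes),
                             cluster_sizes = sizes)
  pat
}

cluster_size_draws <- function(spec) {
  if (spec$n_clusters == 0) return(integer(0))
  if (identical(spec$cluster_sizes, "poisson"))
    return(spec$min_cluster_size +
             stats::rpois(spec$n_clusters, spec$poisson_lambda))
  rep_len(as.integer(spec$cluster_sizes), spec$n_clusters)
}

#' Generate a synthetic cell population with polygons
#'
#' Builds a list of per-cell point patterns: mononucleate cytotrophoblast-
#' like cells (one nucleus in a small square polygon) and multinucleate
#' syncytia (a compact hex-packed group of `k >= 2` nuclei in a larger
#' square polygon). Polygon areas are known exactly, so cytoplasmic area per
#' nucleus and the large-syncytium percentages have analytic ground truth.
#'
#' @param n_mononucleate Number of single-nucleus cells.
#' @param syncytium_sizes Integer vector of nucleus counts, one per
#'   syncytium.
#' @param cell_area_um2 Polygon area of a mononucleate cell, um^2.
#' @param area_per_nucleus_um2 Polygon area per nucleus for syncytia, um^2.
#' @param nucleus_radius,intra_gap Geometry of the nuclear groups, um.
#' @param seed Integer seed.
#' @return List of [point_pattern()] objects with attribute `truth` holding
#'   the expected percentages and areas.
#' @export
generate_cell_population <- function(n_mononucleate = 10,
                                     syncytium_sizes = c(8, 10),
                                     cell_area_um2 = 400,
                                     area_per_nucleus_um2 = 900,
                                     nucleus_radius = 2.5, intra_gap = 0.8,
                                     seed = NULL) {
  stopifnot(n_mononucleate >= 0, all(syncytium_sizes >= 2))
  if (!is.null(seed)) set.seed(seed)
  square <- function(cx, cy, area) {
    s <- sqrt(area) / 2
    cbind(cx + c(-s, s, s, -s), cy + c(-s, -s, s, s))
  }
  pats <- list()
  offset_x <- 0
  for (i in seq_len(n_mononucleate)) {
    s <- sqrt(cell_area_um2)
    cx <- offset_x + s / 2; cy <- s / 2
    offset_x <- offset_x + s + 5
    pats[[length(pats) + 1L]] <-
      point_pattern(cx, cy, nucleus_radius,
                    boundary = square(cx, cy, cell_area_um2),
                    cell_id = sprintf("ctb_%02d", i))
  }
  a <- 2 * nucleus_radius + intra_gap
  for (j in seq_along(syncytium_sizes)) {
    k <- syncytium_sizes[j]
    area <- k * area_per_nucleus_um2
    s <- sqrt(area)
    cx <- offset_x + s / 2; cy <- s / 2
    offset_x <- offset_x + s + 5
    off <- hex_offsets(k, a)
    pats[[length(pats) + 1L]] <-
      point_pattern(cx + off[, 1], cy + off[, 2], nucleus_radius,
                    boundary = square(cx, cy, area),
                    cell_id = sprintf("syn_%02d", j))
  }
  total <- n_mononucleate + sum(syncytium_sizes)
  large <- sum(syncytium_sizes[syncytium_sizes >= 6])
  attr(pats, "truth") <- list(
    pct_nuclei_in_large_syncytia = 100 * large / total,
    mononucleate_area_per_nucleus = cell_area_um2,
    syncytium_area_per_nucleus = area_per_nucleus_um2)
  pats
}

#' Generate lognormal shed-particle areas with ground truth
#'
#' Right-skewed particle areas emulating the shed-material census: most
#' mass in the SNA size range with a long upper tail. The returned vector
#' carries the exact retained/discarded counts at any requested threshold
#' so downstream filtering can be checked against ground truth.
#'
#' @param spec A [generator_spec()] (lognormal parameters and seed).
#' @param n Number of particles (`>= 1`).
#' @param threshold Census threshold recorded in the ground truth, um^2.
#' @return Numeric vector of areas with attribute `truth`: list with
#'   `n_above`, `n_below` (at `threshold`) and the theoretical survival
#'   probability `p_above`.
#' @export
generate_particle_areas <- function(spec = generator_spec(), n = 1000,
                                    threshold = 80) {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  areas <- stats::rlnorm(n, spec$particle_meanlog, spec$particle_sdlog)
  if (spec$particle_sdlog == 0) areas <- rep(exp(spec$particle_meanlog), n)
  attr(areas, "truth") <- list(
    n_above = sum(areas >= threshold),
    n_below = sum(areas < threshold),
    p_above = 1 - plnorm(threshold, spec$particle_meanlog,
                         spec$particle_sdlog))
  areas
}
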