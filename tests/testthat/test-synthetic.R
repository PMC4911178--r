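test_that("planted clusters are recovered exactly in the separable regime", {
  # intra-cluster gaps below half the 3 um threshold, inter-cluster
  # clearance above twice the threshold: recovery must be exact
  spec <- generator_spec(n_clusters = 3, cluster_sizes = 8,
                         intra_cluster_gap = 0.8, background_nuclei = 15,
                         seed = 101)
  pat <- generate_clustered_pattern(spec)
  truth <- attr(pat, "truth")
  snc <- detect_snc(pat)
  expect_identical(snc$n_clusters, 3L)
  expect_identical(sort(snc$sizes), sort(truth$cluster_sizes))
  # membership matches the planted labels exactly
  expect_identical(snc$member, truth$labels > 0)
  for (l in 1:3) {
    planted <- which(truth$labels == l)
    called <- snc$labels[planted]
    expect_identical(length(unique(called)), 1L)
  }
  # background nuclei are never called
  expect_true(all(is.na(snc$labels[truth$labels == 0])))
})

test_that("generators are deterministic given their seed", {
  spec <- generator_spec(seed = 5)
  p1 <- generate_clustered_pattern(spec)
  p2 <- generate_clustered_pattern(spec)
  expect_identical(p1$x, p2$x)
  expect_identical(attr(p1, "truth"), attr(p2, "truth"))
  a1 <- generate_particle_areas(generator_spec(seed = 9), 100)
  a2 <- generate_particle_areas(generator_spec(seed = 9), 100)
  expect_identical(as.numeric(a1), as.numeric(a2))
})

test_that("degenerate generator specs produce the expected edge cases", {
  empty <- generator_spec(n_clusters = 0, background_nuclei = 0, seed = 1)
  pat <- generate_clustered_pattern(empty)
  expect_identical(length(pat$x), 0L)
  # infeasible packing fails loudly
  toobig <- generator_spec(n_clusters = 40, cluster_sizes = 12,
                           inter_cluster_spacing = 120,
                           field = c(300, 300), seed = 1)
  expect_error(generate_clustered_pattern(toobig), "field|place")
  # degenerate lognormal collapses to a point mass
  a <- generate_particle_areas(generator_spec(particle_sdlog = 0, seed = 2),
                               50)
  expect_equal(as.numeric(a), rep(150, 50))
})

test_that("particle areas follow the lognormal survival function", {
  spec <- generator_spec(particle_meanlog = log(150), particle_sdlog = 0.9,
                         seed = 33)
  n <- 1e5
  areas <- generate_particle_areas(spec, n)
  truth <- attr(areas, "truth")
  for (thr in c(40, 80, 200, 900)) {
    p_emp <- mean(areas >= thr)
    p_theo <- 1 - plnorm(thr, log(150), 0.9)
    expect_lt(abs(p_emp - p_theo), 3 * sqrt(p_theo * (1 - p_theo) / n))
  }
  # threshold below the sample minimum retains everything
  expect_identical(length(filter_particles(areas, min(areas) - 1)),
                   as.integer(n))
  # the generated range spans the observed particle scale (80-900 um^2)
  expect_lt(quantile(areas, 0.1), 80)
  expect_gt(quantile(areas, 0.95), 900 / 3)
})

test_that("synthetic cell populations carry analytic ground truth", {
  pop <- generate_cell_population(n_mononucleate = 3,
                                  syncytium_sizes = c(2, 10),
                                  cell_area_um2 = 400,
                                  area_per_nucleus_um2 = 900, seed = 8)
  expect_identical(length(pop), 5L)
  # polygon areas are exact squares
  areas <- vapply(pop, function(p) syncytia:::polygon_area(p$boundary),
                  numeric(1))
  expect_equal(areas, c(rep(400, 3), 2 * 900, 10 * 900))
  # all-mononucleate population has no nuclei in large syncytia
  mono <- generate_cell_population(4, integer(0), seed = 2)
  expect_equal(large_syncytium_stats(mono)$pct_nuclei_in_large_syncytia, 0)
  # a single 10-nucleus syncytium holds 100% of nuclei
  one <- generate_cell_population(0, 10, seed = 3)
  expect_equal(large_syncytium_stats(one)$pct_nuclei_in_large_syncytia, 100)
})
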