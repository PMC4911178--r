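test_that("internuclear distances are edge-to-edge and floored at zero", {
  # two discs of radius 5 with centres 13 um apart: both distances 3 um
  p <- point_pattern(c(0, 13), c(0, 0), radius = 5)
  expect_equal(internuclear_distances(p), c(3, 3))
  # concentric identical discs overlap completely: floored at 0
  p0 <- point_pattern(c(1, 1), c(2, 2), radius = 4)
  expect_equal(internuclear_distances(p0), c(0, 0))
  expect_error(internuclear_distances(point_pattern(1, 1, 2)), "at least 2")
  # excluded nuclei do not participate
  p3 <- point_pattern(c(0, 13, 6.5), c(0, 0, 0), radius = 5,
                      excluded = c(FALSE, FALSE, TRUE))
  expect_equal(internuclear_distances(p3), c(3, 3))
})

test_that("random patterns match the exhaustive all-pairs oracle", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 200
    x <- runif(n, 0, 300); y <- runif(n, 0, 300)
    r <- runif(n, 2, 6)
    p <- point_pattern(x, y, r)
    expect_equal(internuclear_distances(p), nn_edge_oracle(x, y, r))
  }
})

test_that("SNC calls implement the six-nuclei three-micron rule", {
  # chain of 6 with consecutive edge gaps of 2 um (radius 5, centres 12 apart)
  chain6 <- point_pattern(seq(0, by = 12, length.out = 6), rep(0, 6), 5)
  snc <- detect_snc(chain6)
  expect_identical(snc$n_clusters, 1L)
  expect_identical(snc$sizes, 6L)
  expect_true(all(snc$member))
  # five nuclei fall below the size floor
  chain5 <- point_pattern(seq(0, by = 12, length.out = 5), rep(0, 5), 5)
  expect_identical(detect_snc(chain5)$n_clusters, 0L)
  # two tight groups of 6 separated by 50 um are two SNCs
  two <- point_pattern(c(seq(0, by = 12, length.out = 6),
                         seq(150, by = 12, length.out = 6)),
                       rep(0, 12), 5)
  expect_identical(detect_snc(two)$n_clusters, 2L)
  # membership is a partition: labels of members are unique per nucleus
  expect_identical(sum(detect_snc(two)$member), 12L)
  expect_identical(sort(unique(detect_snc(two)$labels[
    !is.na(detect_snc(two)$labels)])), c(1L, 2L))
})

test_that("SNA calls use the ten-nucleus floor and flag protrusion", {
  tight <- function(k, x0 = 0)
    point_pattern(x0 + seq(0, by = 11, length.out = k), rep(0, k), 5)
  expect_identical(detect_sna(tight(10))$n_clusters, 1L)
  expect_identical(detect_sna(tight(9))$n_clusters, 0L)
  expect_false(detect_sna(tight(10))$protrusion_evaluated)
  # planted sizes 12, 10, 4: exactly two SNAs
  spec <- generator_spec(n_clusters = 3, cluster_sizes = c(12, 10, 4),
                         background_nuclei = 0, field = c(500, 500),
                         seed = 77)
  pat <- generate_clustered_pattern(spec)
  expect_identical(detect_sna(pat)$n_clusters, 2L)
})

test_that("cluster calls are invariant under rigid motions", {
  spec <- generator_spec(n_clusters = 2, cluster_sizes = c(8, 6),
                         background_nuclei = 10, seed = 19)
  pat <- generate_clustered_pattern(spec)
  th <- 0.7
  rot <- function(p) point_pattern(cos(th) * p$x - sin(th) * p$y + 40,
                                   sin(th) * p$x + cos(th) * p$y - 15,
                                   p$radius)
  a <- detect_snc(pat); b <- detect_snc(rot(pat))
  expect_identical(a$n_clusters, b$n_clusters)
  expect_identical(a$member, b$member)
  expect_identical(sort(a$sizes), sort(b$sizes))
})

test_that("SNA density and hull areas follow the stated conventions", {
  # 54 clusters over 0.5 mm^2 gives 108 per mm^2: density is count / area
  sp <- generator_spec(n_clusters = 2, cluster_sizes = 10,
                       background_nuclei = 0, seed = 3)
  pat <- generate_clustered_pattern(sp)
  cl <- detect_sna(pat)
  out <- sna_density_and_size(cl, field_area_mm2 = 2 / 108)
  expect_equal(out$density_per_mm2, 108)
  expect_identical(length(out$areas_um2), 2L)
  # a single disc: hull area ~ pi r^2 (1% polygonisation tolerance)
  one <- point_pattern(0, 0, 5)
  a1 <- detect_snc(one, min_size = 1)
  area <- sna_density_and_size(a1, field_area_mm2 = 1)$areas_um2
  expect_equal(area, pi * 25, tolerance = 0.01)
  # no clusters: zero density, empty sizes
  lone <- point_pattern(c(0, 100), c(0, 0), 5)
  out0 <- sna_density_and_size(detect_sna(lone), field_area_mm2 = 0.5)
  expect_equal(out0$density_per_mm2, 0)
  expect_identical(length(out0$areas_um2), 0L)
  expect_error(sna_density_and_size(detect_sna(lone)), "field_area")
})

test_that("large-syncytium statistics aggregate known populations exactly", {
  # square 100x100 um polygon with 4 nuclei: 2500 um^2 per nucleus
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  p4 <- point_pattern(c(40, 52, 40, 52), c(40, 40, 52, 52), 5, boundary = sq)
  st <- large_syncytium_stats(list(p4))
  expect_equal(st$cells$area_per_nucleus_um2, 2500)
  expect_false(st$cells$large)       # 4 < 6 nuclei
  # five nuclei still not large; six are
  p5 <- point_pattern(seq(10, 58, by = 12), rep(50, 5), 5, boundary = sq)
  p6 <- point_pattern(seq(10, 70, by = 12), rep(50, 6), 5, boundary = sq)
  st2 <- large_syncytium_stats(list(p5, p6))
  expect_identical(st2$cells$large, c(FALSE, TRUE))
  expect_equal(st2$pct_nuclei_in_large_syncytia, 100 * 6 / 11)
  # synthetic population with known fractions recovers them exactly
  pop <- generate_cell_population(n_mononucleate = 6,
                                  syncytium_sizes = c(4, 8, 10), seed = 2)
  truth <- attr(pop, "truth")
  st3 <- large_syncytium_stats(pop)
  expect_equal(st3$pct_nuclei_in_large_syncytia,
               truth$pct_nuclei_in_large_syncytia)
  expect_equal(st3$cells$area_per_nucleus_um2[1:6],
               rep(truth$mononucleate_area_per_nucleus, 6))
  # missing polygon: skipped with a warning
  nopoly <- point_pattern(1, 1, 5)
  expect_warning(st4 <- large_syncytium_stats(list(p6, nopoly)), "skipped")
  expect_identical(st4$n_skipped, 1L)
})

test_that("the umbrella report aggregates the standard measurements", {
  pat <- generate_clustered_pattern(generator_spec(
    n_clusters = 2, cluster_sizes = c(12, 6), background_nuclei = 8,
    seed = 61))
  rep <- morphometry_report(pat)
  expect_equal(rep$nn_distances, internuclear_distances(pat))
  expect_identical(rep$snc$n_clusters, 2L)
  expect_identical(rep$sna$n_clusters, 1L)   # only the 12-cluster
  expect_equal(rep$sna_summary$density_per_mm2, 1 / pat$field_area_mm2)
  expect_output(print(rep), "SNCs: 2")
})

test_that("particle filtering is inclusive at the threshold", {
  expect_equal(filter_particles(c(50, 80, 100), 80), c(80, 100))
  expect_identical(length(filter_particles(c(10, 20), 80)), 0L)
  expect_error(filter_particles(c(-5, 10)), "non-negative")
  # large synthetic census against the exact counting ground truth
  areas <- generate_particle_areas(generator_spec(seed = 12), n = 1e4)
  truth <- attr(areas, "truth")
  expect_identical(length(filter_particles(areas, 80)), truth$n_above)
})

test_that("shedding fraction reproduces the worked tissue estimate", {
  expect_equal(round(shedding_fraction(77, 3800), 2), 2.03)
  expect_identical(round(shedding_fraction(77, 3800)), 2)
  expect_equal(shedding_fraction(0, 1234), 0)
  expect_equal(shedding_fraction(55, 55), 100)
  expect_error(shedding_fraction(1, 0), "positive")
})
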