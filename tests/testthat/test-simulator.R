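test_that("target nucleus count converts packing fraction to disc count", {
  expect_identical(target_nucleus_count(250, 1.5, 0.294), 140L)
  expect_identical(target_nucleus_count(250, 1.5, 0), 0L)
  # area pi/40 * 10 * 1.5 / (pi/4) = 1.5, rounds to 2
  expect_identical(target_nucleus_count(10, 1.5, pi / 40), 2L)
  expect_error(target_nucleus_count(10, 1.5, 0.95), "packing")
})

test_that("initial placement is non-overlapping and hits the target count", {
  ps <- sim_params(n_nuclei = 80, seed = 5)
  st <- place_initial_nuclei(ps)
  expect_identical(nrow(st$positions), 80L)
  expect_gte(min(dist(st$positions)), 1)
  # all inside the strip
  expect_true(all(st$positions[, 1] >= 0.5 &
                  st$positions[, 1] <= ps$length - 0.5))
  expect_true(all(st$positions[, 2] >= 0.5))
  # overpacking fails with an informative count
  bad <- sim_params(n_nuclei = 60, length = 20, seed = 1)
  expect_error(place_initial_nuclei(bad, max_attempts = 5000), "placed")
})

test_that("focused fusion sites centre the placement on L/2", {
  ps <- sim_params(n_nuclei = 60, fusion_site_sd = 1, length = 250,
                   seed = 13, injection_mode = "staged", t_end = 0.01)
  sim <- run_simulation(ps)
  # mean of a (near-untruncated) normal at the domain centre
  expect_lt(abs(mean(sim$positions[, 1]) - 125), 3 * 1 / sqrt(60))
})

test_that("the integrator obeys its deterministic limits", {
  flat <- boundary_params(amplitude = 0)
  # zero drift, zero noise, all separations beyond 1 + R, no wall contact:
  # positions unchanged
  dom3 <- syncytium_domain(30, 3, flat)
  ps3 <- sim_params(diffusion = 0, length = 30, mean_thickness = 3,
                    n_nuclei = 10, boundary = flat)
  st <- structure(list(time = 0,
                       positions = cbind(seq(2, 29, by = 3), 1.5),
                       domain = dom3),
                  class = "sim_state")
  st2 <- sim_step(st, ps3, n_steps = 50)
  expect_equal(st2$positions, st$positions, tolerance = 1e-12)
  # overlapping pair relaxes monotonically to contact under gradient flow
  dom <- syncytium_domain(20, 3, flat)
  ps0 <- sim_params(diffusion = 0, length = 20, mean_thickness = 3,
                    n_nuclei = 2, boundary = flat, dt = 5e-4)
  st <- structure(list(time = 0,
                       positions = rbind(c(9.6, 1.5), c(10.4, 1.5)),
                       domain = dom),
                  class = "sim_state")
  seps <- replicate(40, {
    st <<- sim_step(st, ps0, n_steps = 5)
    dist(st$positions)[1]
  })
  expect_true(all(diff(c(0.8, seps)) > -1e-12))
  expect_gte(max(seps), 1 - 1e-6)
  expect_lte(max(seps), 1 + 0.05 + 1e-6)
})

test_that("free diffusion reproduces the 2D mean-squared-displacement law", {
  # S = 0, k_rep ~ 0 and a huge flat channel: effectively free walkers
  n <- 1e4
  D <- 1; t <- 0.5; dt <- 1e-2
  free_pot <- potential_spec(1, 0)
  free_pot$repulsion_stiffness <- 0   # no walls, no core: free walkers
  ps <- sim_params(potential = free_pot,
                   boundary = boundary_params(amplitude = 0),
                   length = 1e5, mean_thickness = 1e4,
                   diffusion = D, n_nuclei = n, dt = dt, t_end = t,
                   snapshot_every = t)
  dom <- syncytium_domain(1e5, 1e4, boundary_params(amplitude = 0))
  start <- cbind(rep(5e4, n), rep(5e3, n))
  st <- structure(list(time = 0, positions = start, domain = dom),
                  class = "sim_state")
  set.seed(17)
  st <- sim_step(st, ps, n_steps = round(t / dt))
  disp <- st$positions - start
  msd <- mean(rowSums(disp^2))
  se <- 4 * D * t / sqrt(n)   # var of per-walker squared displacement
  expect_lt(abs(msd - 4 * D * t), 3 * se)
  # per-coordinate distribution is Normal(0, 2Dt)
  expect_gt(stats::ks.test(disp[, 1], "pnorm", 0, sqrt(2 * D * t))$p.value,
            0.01)
  expect_gt(stats::ks.test(disp[, 2], "pnorm", 0, sqrt(2 * D * t))$p.value,
            0.01)
})

test_that("trajectories are reproducible and nuclei stay confined", {
  ps <- small_params(seed = 23, snapshot_every = 1)
  s1 <- run_simulation(ps)
  s2 <- run_simulation(ps)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$snapshot_positions, s2$snapshot_positions)
  # no escape through any wall over the whole run
  hmax <- max(abs(s1$domain$profile$h(seq(0, ps$length, by = 0.02))))
  for (p in s1$snapshot_positions) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= ps$length))
    expect_true(all(p[, 2] >= -0.5 &
                    p[, 2] <= ps$mean_thickness + hmax + 0.5))
  }
  # final count equals the target in both injection modes
  expect_identical(nrow(s1$positions), 30L)
  s3 <- run_simulation(small_params(seed = 2, injection_mode = "staged"))
  expect_identical(nrow(s3$positions), 30L)
})

test_that("relaxation with D = 0 removes essentially all overlap", {
  ps <- small_params(diffusion = 0, seed = 41)
  sim <- run_simulation(ps)
  overlap <- 1 - min(dist(sim$positions))
  expect_lt(overlap, 0.02)
})
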