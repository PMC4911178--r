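#' Simulation parameters
#'
#' Bundles every parameter of the Brownian-nucleus simulation. All lengths
#' are in nuclear diameters and nuclei have unit diameter; time units are
#' fixed by taking unit mobility, so the diffusion constant `D` is the only
#' kinetic scale.
#'
#' @param potential A [potential_spec()].
#' @param boundary A [boundary_params()].
#' @param length Domain length `L` (default 250).
#' @param mean_thickness Mean strip thickness `T` (default 1.5).
#' @param diffusion Diffusion constant `D` (diameters^2 / time).
#' @param fusion_site_sd Spread `sigma` of the fusion-site distribution
#'   `Normal(L/2, sigma^2)` from which nucleus entry positions are drawn;
#'   `0` or `Inf` means uniform entry positions.
#' @param n_nuclei Target nucleus count (default 140, the count implied by a
#'   29.4% nuclear area fraction in the default strip).
#' @param injection_mode `"start"` places all nuclei at time 0 by
#'   non-overlapping rejection sampling; `"staged"` injects them at uniformly
#'   spaced arrival times over the first half of the run at fusion-site
#'   positions (transient overlaps are resolved by the core repulsion).
#' @param dt Integration time step (default 5e-4). The adhesive well relaxes
#'   at rate `2S/R^2`, so resolved sticking requires `2S/R^2 * dt < 1`; the
#'   default keeps that product at 0.8 for the default `S = 2`.
#' @param t_end Total simulated time (default 50).
#' @param snapshot_every Interval between recorded cluster snapshots
#'   (default 5; use `Inf` to record only the end point).
#' @param seed Integer seed making the whole trajectory reproducible.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(potential = potential_spec(adhesion_strength = 2),
                       boundary = boundary_params(),
                       length = 250, mean_thickness = 1.5,
                       diffusion = 0.125, fusion_site_sd = 0,
                       n_nuclei = 140,
                       injection_mode = c("start", "staged"),
                       dt = 5e-4, t_end = 50, snapshot_every = 5,
                       seed = NULL) {
  injection_mode <- match.arg(injection_mode)
  stopifnot(inherits(potential, "potential_spec"),
            inherits(boundary, "boundary_params"),
            length > 0, mean_thickness > 1,
            diffusion >= 0, fusion_site_sd >= 0,
            n_nuclei >= 1, dt > 0, t_end >= dt, snapshot_every > 0)
  structure(list(potential = potential, boundary = boundary,
                 length = length, mean_thickness = mean_thickness,
                 diffusion = diffusion, fusion_site_sd = fusion_site_sd,
                 n_nuclei = as.integer(n_nuclei),
                 injection_mode = injection_mode,
                 dt = dt, t_end = t_end, snapshot_every = snapshot_every,
                 seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat("  domain: L =", x$length, ", T =", x$mean_thickness,
      ", boundary amplitude A =", x$boundary$amplitude, "\n")
  cat("  potential: S =", x$potential$adhesion_strength,
      ", R =", x$potential$shell_width,
      ", k_rep =", x$potential$repulsion_stiffness, "\n")
  cat("  kinetics: D =", x$diffusion, ", dt =", x$dt, ", t_end =", x$t_end,
      "\n")
  cat("  nuclei:", x$n_nuclei, "(", x$injection_mode, "injection, sigma =",
      if (x$fusion_site_sd %in% c(0, Inf)) "uniform" else x$fusion_site_sd,
      ")\n")
  invisible(x)
}

#' Nucleus count matching a target packing fraction
#'
#' Number of unit-diameter discs whose total area equals `packing_fraction`
#' of the mean-thickness strip `L x T`:
#' `round(packing_fraction * L * T / (pi/4))`. With the defaults `L = 250`,
#' `T = 1.5` and the term nuclear density estimate of 29.4%, this gives 140
#' nuclei.
#'
#' @param length Strip length, diameters.
#' @param mean_thickness Strip mean thickness, diameters.
#' @param packing_fraction Target area fraction in `[0, 0.9069)` (the upper
#'   limit is the hexagonal disc-packing bound).
#' @return Integer count.
#' @examples
#' target_nucleus_count(250, 1.5, 0.294)  # 140
#' @export
target_nucleus_count <- function(length, mean_thickness, packing_fraction) {
  stopifnot(length > 0, mean_thickness > 0, packing_fraction >= 0)
  if (packing_fraction >= pi / sqrt(12))
    stop("packing_fraction exceeds the maximal disc packing (~0.9069)")
  as.integer(round(packing_fraction * length * mean_thickness / (pi / 4)))
}

# draw one entry x-position from the fusion-site distribution, truncated to
# [0.5, L - 0.5] by resampling
draw_entry_x <- function(n, length, sigma) {
  if (sigma == 0 || is.infinite(sigma))
    return(runif(n, 0.5, length - 0.5))
  out <- numeric(0)
  while (base::length(out) < n) {
    cand <- rnorm(n, length / 2, sigma)
    out <- c(out, cand[cand >= 0.5 & cand <= length - 0.5])
  }
  out[seq_len(n)]
}

# draw a y-position uniform in the locally admissible band, NA if the
# channel is too narrow at this x
draw_entry_y <- function(x, domain) {
  top <- domain_top(domain, x) - 0.5
  ifelse(top <= 0.5, NA_real_, runif(base::length(x), 0.5, pmax(top, 0.5)))
}

#' Place the initial nuclei
#'
#' Sequential rejection placement: an x-coordinate is drawn from the
#' fusion-site distribution (uniform when `sigma` is 0 or `Inf`), a
#' y-coordinate uniform within the local channel minus the nuclear radius,
#' and the candidate is rejected if it lies within distance 1 of any accepted
#' nucleus. Fails with an informative error if the target count cannot be
#' placed.
#'
#' @param params A [sim_params()].
#' @param domain A [syncytium_domain()]; built from `params` if missing.
#' @param max_attempts Attempt budget across all placements.
#' @return An object of class `sim_state` with fields `time`, `positions`
#'   (n x 2 matrix) and `domain`.
#' @export
place_initial_nuclei <- function(params, domain = NULL,
                                 max_attempts = 2000 * params$n_nuclei) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(domain))
    domain <- syncytium_domain(params$length, params$mean_thickness,
                               params$boundary)
  n <- params$n_nuclei
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    if (attempts >= max_attempts)
      stop(sprintf(paste0("placement failed after %d attempts: placed %d of ",
                          "%d nuclei (overpacked configuration?)"),
                   attempts, placed, n))
    attempts <- attempts + 1L
    x <- draw_entry_x(1, params$length, params$fusion_site_sd)
    y <- draw_entry_y(x, domain)
    if (is.na(y)) next
    if (placed > 0L) {
      d2 <- (pos[seq_len(placed), 1] - x)^2 + (pos[seq_len(placed), 2] - y)^2
      if (min(d2) < 1) next
    }
    placed <- placed + 1L
    pos[placed, ] <- c(x, y)
  }
  structure(list(time = 0, positions = pos, domain = domain),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("Simulation state: t =", x$time, ",", nrow(x$positions), "nuclei\n")
  invisible(x)
}

# shared driver over the compiled core
run_core <- function(positions, entry_step, n_steps, params, domain,
                     snapshot_steps = integer(0)) {
  tab <- profile_table(domain)
  .bd_run_cpp(positions, as.integer(entry_step), as.integer(n_steps),
              params$dt,
              params$potential$repulsion_stiffness,
              params$potential$adhesion_strength,
              params$potential$shell_width,
              params$diffusion,
              params$length, params$mean_thickness,
              tab$h, tab$x0, tab$dx,
              as.integer(snapshot_steps))
}

#' Advance a simulation state
#'
#' Performs `n_steps` Euler-Maruyama updates
#' `dx_i = F_i dt + sqrt(2 D dt) xi_i` with unit mobility, where `F_i` sums
#' the pairwise contact forces and the membrane forces, and `xi_i` is
#' standard Gaussian noise per coordinate.
#'
#' @param state A `sim_state` from [place_initial_nuclei()].
#' @param params A [sim_params()].
#' @param n_steps Number of steps (default 1).
#' @return The updated `sim_state`.
#' @export
sim_step <- function(state, params, n_steps = 1) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "sim_params"))
  out <- run_core(state$positions, rep(0L, nrow(state$positions)),
                  n_steps, params, state$domain)
  state$positions <- out$positions
  state$time <- state$time + n_steps * params$dt
  state
}

#' Run a full simulation
#'
#' Places (or stages the injection of) the nuclei, integrates the overdamped
#' Brownian dynamics to `t_end`, and records connected-cluster snapshots at
#' the configured cadence. The trajectory is fully reproducible from the
#' seed in `params`.
#'
#' In `"staged"` mode, nuclei enter at uniformly spaced arrival times over
#' the first half of the run at positions drawn from the fusion-site
#' distribution; before its arrival a nucleus neither moves nor interacts.
#'
#' @param params A [sim_params()].
#' @param domain Optional pre-built [syncytium_domain()].
#' @return An object of class `syncytium_sim` with the final state, per-
#'   snapshot [find_clusters()] assignments, snapshot times and positions.
#' @examples
#' ps <- sim_params(n_nuclei = 30, length = 50, t_end = 2, seed = 7)
#' sim <- run_simulation(ps)
#' summary(sim)
#' @export
run_simulation <- function(params, domain = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(domain))
    domain <- syncytium_domain(params$length, params$mean_thickness,
                               params$boundary)
  n_steps <- as.integer(round(params$t_end / params$dt))
  snap_t <- seq(0, params$t_end, by = min(params$snapshot_every, params$t_end))
  if (snap_t[length(snap_t)] < params$t_end) snap_t <- c(snap_t, params$t_end)
  snap_steps <- as.integer(round(snap_t / params$dt))

  if (params$injection_mode == "start") {
    st <- place_initial_nuclei(params, domain)
    positions <- st$positions
    entry <- rep(0L, params$n_nuclei)
  } else {
    n <- params$n_nuclei
    arrival <- seq(0, params$t_end / 2, length.out = n)
    entry <- as.integer(floor(arrival / params$dt))
    x <- draw_entry_x(n, params$length, params$fusion_site_sd)
    y <- draw_entry_y(x, domain)
    while (anyNA(y)) {  # resample x where the channel is too narrow
      bad <- is.na(y)
      x[bad] <- draw_entry_x(sum(bad), params$length, params$fusion_site_sd)
      y[bad] <- draw_entry_y(x[bad], domain)
    }
    positions <- cbind(x, y)
  }

  out <- run_core(positions, entry, n_steps, params, domain, snap_steps)
  snaps <- out$snapshots
  R <- params$potential$shell_width
  assignments <- vector("list", length(snaps))
  for (k in seq_along(snaps)) {
    active <- entry <= snap_steps[k]
    assignments[[k]] <- if (any(active))
      cluster_nuclei(snaps[[k]][active, , drop = FALSE], R)
    else
      find_clusters(matrix(FALSE, 0, 0))
  }
  structure(list(params = params, domain = domain,
                 positions = out$positions,
                 snapshot_times = snap_t,
                 snapshot_positions = snaps,
                 snapshot_entry = entry,
                 clusters = assignments,
                 final_clusters = assignments[[length(assignments)]]),
            class = "syncytium_sim")
}

#' @export
print.syncytium_sim <- function(x, ...) {
  cl <- x$final_clusters
  cat("Syncytium simulation:", nrow(x$positions), "nuclei, t_end =",
      x$params$t_end, "\n")
  cat("  final clusters:", sum(cl$sizes >= 2), "of >= 2 nuclei;",
      sum(cl$sizes > 6), "of > 6 nuclei\n")
  cat("  mass-weighted mean cluster size:",
      round(mean_cluster_size_per_nucleus(cl), 3), "\n")
  invisible(x)
}

#' @export
summary.syncytium_sim <- function(object, ...) {
  cl <- object$clusters
  df <- data.frame(
    time = object$snapshot_times,
    n_nuclei = vapply(cl, function(a) a$n_nuclei, integer(1)),
    clusters_ge2 = vapply(cl, cluster_census, integer(1), min_size = 2),
    clusters_gt6 = vapply(cl, cluster_census, integer(1), min_size = 7),
    mean_size_per_nucleus = vapply(cl, function(a)
      if (a$n_nuclei > 0) mean_cluster_size_per_nucleus(a) else NA_real_,
      numeric(1)))
  class(df) <- c("summary.syncytium_sim", "data.frame")
  df
}

#' Plot a simulated configuration
#'
#' Draws the strip boundaries and the nuclei as unit-diameter discs coloured
#' by cluster membership (grey = singleton), in the style of a model
#' visualisation snapshot.
#'
#' @param x A `syncytium_sim`.
#' @param xlim Optional x-window, diameters.
#' @param ... Passed to [graphics::symbols()].
#' @return `x`, invisibly.
#' @export
plot.syncytium_sim <- function(x, xlim = NULL, ...) {
  draw_configuration(x$positions, x$domain, x$final_clusters, xlim = xlim, ...)
  invisible(x)
}

draw_configuration <- function(positions, domain, assignment = NULL,
                               xlim = NULL, ...) {
  if (is.null(xlim)) xlim <- c(0, domain$length)
  xs <- seq(xlim[1], xlim[2], length.out = 400)
  top <- domain_top(domain, xs)
  plot.default(NA, xlim = xlim,
               ylim = c(-0.5, max(top) + 0.5),
               xlab = "x (nuclear diameters)", ylab = "y",
               asp = 1, type = "n")
  lines(xs, top, col = "steelblue")
  lines(xlim, c(0, 0), col = "steelblue")
  if (nrow(positions) > 0) {
    col <- "grey70"
    if (!is.null(assignment)) {
      sz <- assignment$sizes[assignment$labels]
      pal <- hcl.colors(max(assignment$labels), "Dark 3")
      col <- ifelse(sz >= 2, pal[assignment$labels], "grey70")
    }
    symbols(positions[, 1], positions[, 2], circles = rep(0.5, nrow(positions)),
            inches = FALSE, add = TRUE, bg = col, fg = "grey30", ...)
  }
  invisible(NULL)
}

#' Export a trajectory snapshot table
#'
#' Writes the recorded snapshots as a tidy table with columns
#' `time, nucleus_id, x, y`.
#'
#' @param sim A `syncytium_sim`.
#' @param path Output CSV path.
#' @return The data frame, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "syncytium_sim"))
  rows <- lapply(seq_along(sim$snapshot_times), function(k) {
    p <- sim$snapshot_positions[[k]]
    data.frame(time = sim$snapshot_times[k], nucleus_id = seq_len(nrow(p)),
               x = p[, 1], y = p[, 2])
  })
  df <- do.call(rbind, rows)
  write_table_with_provenance(df, path, sim$params)
  invisible(df)
}
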