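#' Scenario sweep specification
#'
#' Defines one of the four replicated scenario sweeps over the model
#' parameters:
#' \describe{
#'   \item{`adhesion`}{varies the stickiness `S`;}
#'   \item{`diffusion`}{varies the diffusion constant `D`, co-varying `S` so
#'     that the dimensionless well depth `S/D` stays at its base value (see
#'     [covary_adhesion_with_diffusion()]);}
#'   \item{`fusion_sites`}{varies the fusion-site spread `sigma` (use `Inf`
#'     for uniform entry positions); runs in staged-injection mode, since
#'     fusion events deposit nuclei over time and tightly focused sites are
#'     geometrically incompatible with all-at-start non-overlapping
#'     placement;}
#'   \item{`amplitude`}{varies the boundary-roughness multiplier `A`.}
#' }
#'
#' @param scenario One of `"adhesion"`, `"diffusion"`, `"fusion_sites"`,
#'   `"amplitude"`.
#' @param values Non-empty numeric grid of parameter values. Defaults per
#'   scenario: `S` in `c(0.25, 0.5, 1, 2)` (one decade below the base
#'   stickiness, all within the resolved-well regime `2S/R^2 dt < 1`), `D`
#'   in `c(0.0125, 0.04, 0.125, 0.4, 1.25)` (two decades around base),
#'   `sigma` in `c(10, 25, 50, 100, Inf)` (chosen so the cluster census at
#'   the tightest focus stays below the whole-population ceiling and the
#'   grid ends at uniform entry), `A` in `c(0, 0.5, 1, 2)`.
#' @param n_replicates Independent replicates per grid value (`>= 2`);
#'   default 50 (desk scale; the full-scale study uses 500).
#' @param base_params A [sim_params()] providing every non-swept parameter.
#' @param master_seed Integer; per-replicate seeds are derived from it
#'   deterministically.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(scenario = c("adhesion", "diffusion", "fusion_sites",
                                    "amplitude"),
                       values = NULL, n_replicates = 50,
                       base_params = sim_params(), master_seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(values))
    values <- switch(scenario,
                     adhesion = c(0.25, 0.5, 1, 2),
                     diffusion = c(0.0125, 0.04, 0.125, 0.4, 1.25),
                     fusion_sites = c(10, 25, 50, 100, Inf),
                     amplitude = c(0, 0.5, 1, 2))
  stopifnot(length(values) >= 1, n_replicates >= 2,
            inherits(base_params, "sim_params"))
  if (scenario == "diffusion" && any(values <= 0))
    stop("diffusion grid values must be positive")
  structure(list(scenario = scenario, values = values,
                 n_replicates = as.integer(n_replicates),
                 base_params = base_params,
                 master_seed = as.integer(master_seed)),
            class = "sweep_spec")
}

#' Co-vary adhesion with diffusion
#'
#' For the diffusion scenario both `S` and `D` must change together to keep
#' the overall adhesiveness fixed while the rate of movement varies. The
#' rule used is a constant dimensionless well depth:
#' `S(D) = base_S * D / base_D`, so `S/D` (the escape-probability scale of
#' an overdamped particle in a well at temperature `D`) is the same at every
#' grid point.
#'
#' @param D_values Positive diffusion grid.
#' @param base_S,base_D Base stickiness and diffusion constants.
#' @return Data frame with columns `D` and `S`.
#' @examples
#' covary_adhesion_with_diffusion(c(0.25, 0.5), base_S = 1, base_D = 0.25)
#' @export
covary_adhesion_with_diffusion <- function(D_values, base_S, base_D) {
  stopifnot(base_D > 0)
  if (any(D_values <= 0)) stop("diffusion grid values must be positive")
  data.frame(D = D_values, S = base_S * D_values / base_D)
}

# apply one grid value of a scenario to the base parameters
scenario_params <- function(spec, value, seed) {
  p <- spec$base_params
  p$seed <- seed
  switch(spec$scenario,
         adhesion = {
           p$potential$adhesion_strength <- value
         },
         diffusion = {
           ss <- covary_adhesion_with_diffusion(
             value, p$potential$adhesion_strength, p$diffusion)
           p$diffusion <- ss$D
           p$potential$adhesion_strength <- ss$S
         },
         fusion_sites = {
           p$fusion_site_sd <- if (is.infinite(value)) 0 else value
           p$injection_mode <- "staged"
         },
         amplitude = {
           p$boundary$amplitude <- value
         })
  p
}

#' Run a replicated scenario sweep
#'
#' Executes `n_replicates` independent simulations at every grid value
#' (deterministic per-replicate seeds derived from the master seed), computes
#' per-replicate cluster metrics at the end point, and aggregates them into
#' per-value means with 95% t-intervals. Replicate failures are caught,
#' recorded and reported; the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param verbose Print per-value progress lines.
#' @return An object of class `sweep_result` with `results` (tidy
#'   per-replicate rows), `aggregate` (per-value summaries), `failures`
#'   (count) and the spec.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  set.seed(spec$master_seed)
  n_total <- length(spec$values) * spec$n_replicates
  seeds <- sample.int(.Machine$integer.max, n_total)
  rows <- vector("list", n_total)
  failures <- 0L
  k <- 0L
  for (vi in seq_along(spec$values)) {
    value <- spec$values[vi]
    if (verbose)
      message(sprintf("sweep %s: value %g (%d/%d)",
                      spec$scenario, value, vi, length(spec$values)))
    for (r in seq_len(spec$n_replicates)) {
      k <- k + 1L
      p <- scenario_params(spec, value, seeds[k])
      met <- tryCatch({
        sim <- run_simulation(p)
        cl <- sim$final_clusters
        c(mean_size_per_nucleus = mean_cluster_size_per_nucleus(cl),
          mean_size = mean_cluster_size(cl),
          clusters_ge2 = cluster_census(cl, 2),
          clusters_gt6 = cluster_census(cl, 7))
      }, error = function(e) {
        warning(sprintf("replicate failed (value %g, rep %d): %s",
                        value, r, conditionMessage(e)), call. = FALSE)
        c(mean_size_per_nucleus = NA_real_, mean_size = NA_real_,
          clusters_ge2 = NA_real_, clusters_gt6 = NA_real_)
      })
      if (anyNA(met)) failures <- failures + 1L
      rows[[k]] <- data.frame(scenario = spec$scenario, value = value,
                              replicate = r, seed = seeds[k], t(met))
    }
  }
  results <- do.call(rbind, rows)
  structure(list(spec = spec, results = results,
                 aggregate = aggregate_sweep(results),
                 failures = failures),
            class = "sweep_result")
}

# per-value mean and 95% t-interval for every metric column
aggregate_sweep <- function(results) {
  metrics <- c("mean_size_per_nucleus", "mean_size",
               "clusters_ge2", "clusters_gt6")
  vals <- unique(results$value)
  out <- lapply(vals, function(v) {
    sub <- results[results$value == v, , drop = FALSE]
    row <- data.frame(scenario = sub$scenario[1], value = v,
                      n = sum(!is.na(sub$mean_size_per_nucleus)))
    for (m in metrics) {
      x <- sub[[m]][!is.na(sub[[m]])]
      mu <- mean(x)
      half <- if (length(x) > 1)
        qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x)) else NA_real_
      row[[paste0(m, "_mean")]] <- mu
      row[[paste0(m, "_lo")]] <- mu - half
      row[[paste0(m, "_hi")]] <- mu + half
    }
    row
  })
  do.call(rbind, out)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Scenario sweep:", x$spec$scenario, "over",
    length(x$spec$values), "values x", x$spec$n_replicates, "replicates\n")
  if (x$failures > 0) cat("  failed replicates:", x$failures, "\n")
  agg <- x$aggregate
  cat("  mass-weighted mean cluster size by value:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    %8g  %8.3f  [%.3f, %.3f]\n", agg$value[i],
                agg$mean_size_per_nucleus_mean[i],
                agg$mean_size_per_nucleus_lo[i],
                agg$mean_size_per_nucleus_hi[i]))
  invisible(x)
}

#' @export
summary.sweep_result <- function(object, ...) object$aggregate

#' Plot aggregated sweep results
#'
#' Mass-weighted mean cluster size (with 95% interval bars) against the
#' swept parameter.
#'
#' @param x A `sweep_result`.
#' @param log Axis log spec passed to [graphics::plot.default()] (e.g.
#'   `"x"`).
#' @param ... Further plot arguments.
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, log = "", ...) {
  agg <- x$aggregate
  v <- agg$value
  finite <- is.finite(v)
  xlab <- switch(x$spec$scenario,
                 adhesion = "stickiness S",
                 diffusion = "diffusion constant D",
                 fusion_sites = "fusion-site spread sigma",
                 amplitude = "boundary amplitude A")
  plot.default(v[finite], agg$mean_size_per_nucleus_mean[finite], log = log,
               xlab = xlab, ylab = "mean cluster size per nucleus",
               pch = 19, ylim = range(agg$mean_size_per_nucleus_lo,
                                      agg$mean_size_per_nucleus_hi,
                                      na.rm = TRUE), ...)
  arrows(v[finite], agg$mean_size_per_nucleus_lo[finite],
         v[finite], agg$mean_size_per_nucleus_hi[finite],
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Export sweep tables
#'
#' Writes tidy per-replicate rows and the aggregated summary as CSV with a
#' provenance header.
#'
#' @param result A `sweep_result`.
#' @param path Per-replicate output path; the aggregate table goes to the
#'   same name with suffix `"_aggregate"`.
#' @return Invisibly, the per-replicate data frame.
#' @export
write_sweep_result <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  write_table_with_provenance(result$results, path,
                              result$spec$base_params,
                              seed = result$spec$master_seed)
  agg_path <- sub("(\\.[^.]+)?$", "_aggregate\\1", path)
  write_table_with_provenance(result$aggregate, agg_path,
                              result$spec$base_params,
                              seed = result$spec$master_seed)
  invisible(result$results)
}
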