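# Config schema: every known key with its default. Defaults follow the
# stated model geometry: L = 250 diameters, T = 1.5, R = 0.05, 140 nuclei,
# boundary variation within 0.75 diameters with 99.7% confidence.
config_schema <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    output_dir = ".",
    log_level = "info",
    simulation = list(
      length = 250, mean_thickness = 1.5, diffusion = 0.125,
      fusion_site_sd = 0, n_nuclei = 140L, injection_mode = "start",
      dt = 5e-4, t_end = 50, snapshot_every = 5),
    potential = list(
      repulsion_stiffness = 100, adhesion_strength = 2, shell_width = 0.05),
    boundary = list(
      stationary_sd = 0.25, reversion_rate = 0.2, sample_spacing = 2.5,
      amplitude = 1),
    sweep = list(
      scenario = "adhesion", values = NULL, n_replicates = 50L),
    generate = list(
      n_clusters = 3L, cluster_sizes = 8L, intra_cluster_gap = 0.8,
      inter_cluster_spacing = 60, background_nuclei = 20,
      nucleus_radius = 2.5, field = c(400, 400)),
    analyze = list(
      pattern_file = NULL, snc_gap = 3, snc_min_size = 6L,
      sna_min_size = 10L, particle_threshold = 80))
}

merge_validated <- function(user, schema, where = "") {
  if (is.null(user)) return(schema)
  if (!is.list(user)) stop(sprintf("config section '%s' must be a mapping",
                                   where))
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown))
    stop(sprintf("unknown config key '%s%s'", where, unknown[1]))
  for (k in names(user)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      schema[[k]] <- merge_validated(user[[k]], schema[[k]],
                                     paste0(where, k, "/"))
    } else {
      schema[k] <- list(user[[k]])   # preserves explicit nulls
    }
  }
  schema
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (naming the
#' offending key and section), and fills every omitted key with its default.
#' Defaults are the stated model values: domain length 250 diameters, mean
#' thickness 1.5, shell width R = 0.05, 140 nuclei, and an OU boundary whose
#' variation stays within 0.75 diameters with 99.7% confidence.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list with sections `simulation`,
#'   `potential`, `boundary`, `sweep`, `generate`, `analyze`.
#' @examples
#' cfg <- load_config(system.file("extdata", "example-config.yaml",
#'                                package = "syncytia"))
#' cfg$simulation$length   # defaults filled: 250
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  user <- yaml::read_yaml(path)
  cfg <- merge_validated(user, config_schema())
  if (!cfg$mode %in% c("simulate", "sweep", "analyze", "generate"))
    stop(sprintf("unknown mode '%s'", cfg$mode))
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param config A `run_config` (or plain list using the same keys).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration: mode =", x$mode, ", seed =", x$seed, "\n")
  cat("  domain: L =", x$simulation$length, ", T =",
      x$simulation$mean_thickness, ", nuclei =", x$simulation$n_nuclei, "\n")
  invisible(x)
}

# build sim_params from a validated config
config_sim_params <- function(cfg) {
  sim_params(
    potential = potential_spec(cfg$potential$repulsion_stiffness,
                               cfg$potential$adhesion_strength,
                               cfg$potential$shell_width),
    boundary = boundary_params(cfg$boundary$stationary_sd,
                               cfg$boundary$reversion_rate,
                               cfg$boundary$sample_spacing,
                               cfg$boundary$amplitude),
    length = cfg$simulation$length,
    mean_thickness = cfg$simulation$mean_thickness,
    diffusion = cfg$simulation$diffusion,
    fusion_site_sd = cfg$simulation$fusion_site_sd,
    n_nuclei = cfg$simulation$n_nuclei,
    injection_mode = cfg$simulation$injection_mode,
    dt = cfg$simulation$dt, t_end = cfg$simulation$t_end,
    snapshot_every = cfg$simulation$snapshot_every,
    seed = cfg$seed)
}

#' Execute a run configuration
#'
#' Dispatches on `mode`: `"simulate"` runs one simulation, `"sweep"` a
#' replicated scenario sweep, `"generate"` a synthetic clustered pattern,
#' and `"analyze"` the morphometric report on a point-pattern table.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @param verbose Print progress.
#' @return The mode's result object.
#' @export
run_config <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  switch(config$mode,
         simulate = run_simulation(config_sim_params(config)),
         sweep = run_sweep(sweep_spec(config$sweep$scenario,
                                      config$sweep$values,
                                      config$sweep$n_replicates,
                                      config_sim_params(config),
                                      master_seed = config$seed),
                           verbose = verbose),
         generate = {
           g <- config$generate
           generate_clustered_pattern(generator_spec(
             n_clusters = g$n_clusters, cluster_sizes = g$cluster_sizes,
             intra_cluster_gap = g$intra_cluster_gap,
             inter_cluster_spacing = g$inter_cluster_spacing,
             background_nuclei = g$background_nuclei,
             nucleus_radius = g$nucleus_radius, field = g$field,
             seed = config$seed))
         },
         analyze = {
           a <- config$analyze
           if (is.null(a$pattern_file))
             stop("analyze mode requires analyze/pattern_file")
           pat <- read_point_pattern(a$pattern_file)
           list(nn_distances = internuclear_distances(pat),
                snc = detect_snc(pat, a$snc_gap, a$snc_min_size),
                sna = detect_sna(pat, a$snc_gap, a$sna_min_size))
         })
}

#' Render a configuration snapshot to an image
#'
#' Draws the strip boundaries and the nuclei as discs coloured by cluster
#' membership to a PNG file; an empty state yields a boundary-only image.
#'
#' @param state A `syncytium_sim`, a `sim_state`, or an n x 2 position
#'   matrix.
#' @param path Output PNG path.
#' @param domain Required [syncytium_domain()] when `state` is a bare
#'   matrix.
#' @param xlim Optional x-window.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, path, domain = NULL, xlim = NULL,
                            width = 1600, height = 300) {
  if (inherits(state, "syncytium_sim")) {
    positions <- state$positions
    domain <- state$domain
    assignment <- state$final_clusters
  } else if (inherits(state, "sim_state")) {
    positions <- state$positions
    domain <- state$domain
    assignment <- if (nrow(positions)) cluster_nuclei(positions) else NULL
  } else {
    positions <- as.matrix(state)
    if (is.null(domain)) stop("a domain is required for bare positions")
    assignment <- if (nrow(positions)) cluster_nuclei(positions) else NULL
  }
  ok <- tryCatch({
    png(path, width = width, height = height)
    TRUE
  }, error = function(e)
    stop(sprintf("cannot write image to '%s': %s", path,
                 conditionMessage(e))))
  on.exit(dev.off())
  op <- par(mar = c(3, 3, 1, 1))
  on.exit(par(op), add = TRUE)
  draw_configuration(positions, domain, assignment, xlim = xlim)
  invisible(path)
}

#' Write a tidy table with a provenance header
#'
#' Prepends comment lines recording the package version, the seed and a
#' parameter digest, then the CSV body (UTF-8, header row).
#'
#' @param df Data frame.
#' @param path Output path.
#' @param params Parameter object included in the digest.
#' @param seed Seed recorded in the header (taken from `params` if absent).
#' @return `path`, invisibly.
#' @export
write_table_with_provenance <- function(df, path, params = NULL,
                                        seed = NULL) {
  if (is.null(seed) && !is.null(params$seed)) seed <- params$seed
  digest <- if (!is.null(params)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    dput(params, file = tmp)
    unname(tools::md5sum(tmp))
  } else NA_character_
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("# syncytia %s", as.character(packageVersion("syncytia"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else seed),
    sprintf("# params_md5: %s", digest)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written with a provenance header
#'
#' @param path Input path.
#' @return Data frame; the header lines are attached as attribute
#'   `provenance`.
#' @export
read_table_with_provenance <- function(path) {
  lines <- readLines(path, n = 10)
  prov <- lines[startsWith(lines, "#")]
  df <- read.csv(path, comment.char = "#")
  attr(df, "provenance") <- prov
  df
}

#' Read a nuclear point pattern from a delimited table
#'
#' Expects columns `x_um`, `y_um`, `radius_um` and optionally `cell_id`,
#' `excluded_flag` (0/1). Comment lines starting with `#` are skipped.
#'
#' @param path CSV path.
#' @param field_area_mm2 Optional field area attached to the pattern.
#' @return A [point_pattern()].
#' @export
read_point_pattern <- function(path, field_area_mm2 = NULL) {
  df <- read.csv(path, comment.char = "#")
  need <- c("x_um", "y_um", "radius_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("pattern table lacks column '%s'", miss[1]))
  excl <- if ("excluded_flag" %in% names(df)) df$excluded_flag > 0 else NULL
  point_pattern(df$x_um, df$y_um, df$radius_um,
                field_area_mm2 = field_area_mm2, excluded = excl,
                cell_id = if ("cell_id" %in% names(df)) df$cell_id[1]
                          else NULL)
}

#' Write a nuclear point pattern as a delimited table
#'
#' @param pattern A [point_pattern()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- data.frame(
    cell_id = if (is.null(pattern$cell_id)) NA else pattern$cell_id,
    nucleus_id = seq_along(pattern$x),
    x_um = pattern$x, y_um = pattern$y, radius_um = pattern$radius,
    excluded_flag = as.integer(pattern$excluded))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
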