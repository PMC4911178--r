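#' Parameters of the corrugated upper boundary
#'
#' The roughness of the syncytium's upper boundary is modelled as a
#' zero-mean Ornstein-Uhlenbeck (OU) process subsampled at regular knots and
#' interpolated by a cubic spline, giving a smooth random thickness profile.
#' The stationary standard deviation defaults to 0.25 nuclear diameters so
#' that, by the Gaussian three-sigma rule, the variation stays within
#' +/- 0.75 diameters with 99.7% confidence. The `amplitude` multiplier `A`
#' scales the whole profile and is the quantity varied in the
#' boundary-amplitude scenario.
#'
#' @param stationary_sd Stationary SD of the OU heights, nuclear diameters.
#' @param reversion_rate Mean-reversion rate theta (1/diameters); the
#'   correlation length of the roughness is `1/theta` (default 5 diameters).
#' @param sample_spacing Spacing between OU knots, diameters (default 2.5).
#' @param amplitude Dimensionless multiplier `A` applied to all heights
#'   (`A = 0` gives a perfectly flat boundary).
#' @return An object of class `boundary_params`.
#' @export
boundary_params <- function(stationary_sd = 0.25,
                            reversion_rate = 0.2,
                            sample_spacing = 2.5,
                            amplitude = 1) {
  stopifnot(stationary_sd > 0, reversion_rate > 0, sample_spacing > 0,
            amplitude >= 0)
  structure(list(stationary_sd = stationary_sd,
                 reversion_rate = reversion_rate,
                 sample_spacing = sample_spacing,
                 amplitude = amplitude),
            class = "boundary_params")
}

#' Sample boundary heights from the stationary OU process
#'
#' Draws `floor(length / sample_spacing) + 1` knot heights at regular spacing
#' from the stationary OU process using the exact Gaussian transition
#' density (no Euler discretisation bias): `h_1 ~ N(0, s^2)` and
#' `h_{k+1} | h_k ~ N(rho h_k, s^2 (1 - rho^2))` with
#' `rho = exp(-theta * spacing)`. Heights are scaled by the amplitude `A`.
#'
#' @param params A [boundary_params()].
#' @param length Domain length in nuclear diameters.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return Numeric vector of knot heights with attribute `x` holding knot
#'   positions.
#' @export
sample_ou_knots <- function(params = boundary_params(), length = 250,
                            seed = NULL) {
  stopifnot(inherits(params, "boundary_params"), length > 0)
  if (!is.null(seed)) set.seed(seed)
  xs <- seq(0, length, by = params$sample_spacing)
  if (xs[base::length(xs)] < length) xs <- c(xs, length)
  n <- base::length(xs)
  s <- params$stationary_sd
  h <- numeric(n)
  h[1] <- rnorm(1, 0, s)
  if (n > 1) {
    gaps <- diff(xs)
    rho <- exp(-params$reversion_rate * gaps)
    innov <- rnorm(n - 1)
    for (k in seq_len(n - 1))
      h[k + 1] <- rho[k] * h[k] + s * sqrt(1 - rho[k]^2) * innov[k]
  }
  structure(params$amplitude * h, x = xs)
}

#' Interpolate a boundary profile through knot heights
#'
#' Fits a natural cubic spline through the knots, giving a continuous height
#' function `h(x)` with continuous first derivative that passes through every
#' knot exactly.
#'
#' @param knot_heights Numeric heights; if produced by [sample_ou_knots()]
#'   the positions are taken from its `x` attribute, otherwise supply
#'   `knot_positions`.
#' @param knot_positions Optional numeric vector of x-positions.
#' @return An object of class `boundary_profile` with elements
#'   `knot_positions`, `knot_heights` and the interpolant `h` (a function).
#' @export
interpolate_profile <- function(knot_heights, knot_positions = NULL) {
  if (is.null(knot_positions)) knot_positions <- attr(knot_heights, "x")
  if (is.null(knot_positions))
    stop("knot_positions are required when heights carry no 'x' attribute")
  if (length(knot_heights) < 2 || length(knot_positions) < 2)
    stop("at least 2 knots are required to interpolate a boundary profile")
  stopifnot(length(knot_heights) == length(knot_positions))
  h <- splinefun(knot_positions, as.numeric(knot_heights), method = "natural")
  structure(list(knot_positions = as.numeric(knot_positions),
                 knot_heights = as.numeric(knot_heights),
                 h = h),
            class = "boundary_profile")
}

#' Confinement fraction of the boundary variation
#'
#' Monte-Carlo estimate of `P(|h| < bound) * 100` under stationary sampling
#' of the amplitude-scaled OU boundary heights. With the default stationary
#' SD of 0.25 diameters and `A = 1` the variation stays within +/- 0.75
#' diameters about 99.7% of the time (three-sigma rule).
#'
#' @param params A [boundary_params()].
#' @param n_samples Number of stationary draws (`>= 1e4`).
#' @param seed Optional integer seed.
#' @param bound Confinement half-width in diameters (default 0.75).
#' @return Percentage in `[0, 100]`.
#' @export
confinement_fraction <- function(params = boundary_params(),
                                 n_samples = 1e5, seed = NULL,
                                 bound = 0.75) {
  stopifnot(n_samples >= 1e4)
  if (params$amplitude == 0) return(100)
  h <- sample_ou_knots(params, length = n_samples * params$sample_spacing,
                       seed = seed)
  h <- h[seq_len(n_samples)]
  100 * mean(abs(h) < bound)
}

#' Syncytium domain: a corrugated strip
#'
#' The simulated cross-section of the syncytiotrophoblast layer: a strip of
#' length `L` (default 250 nuclear diameters) with a flat lower boundary at
#' `y = 0` and upper boundary `y = T + A h(x)` where `T` is the mean
#' thickness (default 1.5 diameters) and `h` the interpolated OU profile.
#'
#' @param length Domain length `L`, diameters.
#' @param mean_thickness Mean thickness `T`, diameters; must exceed 1 so a
#'   unit-diameter nucleus fits.
#' @param boundary A [boundary_params()] describing the upper-profile
#'   roughness.
#' @param seed Optional seed used to draw the profile.
#' @param profile Optionally a ready-made [interpolate_profile()] object; if
#'   supplied, `boundary`/`seed` are not used to draw knots.
#' @return An object of class `syncytium_domain`.
#' @examples
#' dom <- syncytium_domain(seed = 1)
#' range(dom$profile$knot_heights)
#' @export
syncytium_domain <- function(length = 250, mean_thickness = 1.5,
                             boundary = boundary_params(), seed = NULL,
                             profile = NULL) {
  stopifnot(length > 0, mean_thickness > 1)
  if (is.null(profile)) {
    kn <- sample_ou_knots(boundary, length = length, seed = seed)
    profile <- interpolate_profile(kn)
  }
  stopifnot(inherits(profile, "boundary_profile"))
  structure(list(length = length,
                 mean_thickness = mean_thickness,
                 boundary = boundary,
                 profile = profile),
            class = "syncytium_domain")
}

# vertical position of the upper boundary at x (amplitude already folded
# into the sampled knot heights)
domain_top <- function(domain, x) {
  domain$mean_thickness + domain$profile$h(x)
}

#' @export
print.syncytium_domain <- function(x, ...) {
  cat("Syncytium domain: L =", x$length, "diameters, mean thickness T =",
      x$mean_thickness, "\n")
  cat("  upper profile:", length(x$profile$knot_positions),
      "OU knots, height range [",
      round(min(x$profile$knot_heights), 3), ",",
      round(max(x$profile$knot_heights), 3), "]\n")
  invisible(x)
}

# tabulate the upper profile for the compiled dynamics core
profile_table <- function(domain, dx = 0.05) {
  xs <- seq(0, domain$length, by = dx)
  list(h = domain$profile$h(xs), x0 = 0, dx = dx)
}

#' Export a boundary profile as a two-column table
#'
#' @param domain A [syncytium_domain()].
#' @param path Output file (CSV with columns `x`, `height`).
#' @param dx Sampling interval along x.
#' @return The data frame, invisibly.
#' @export
write_boundary_profile <- function(domain, path, dx = 0.5) {
  xs <- seq(0, domain$length, by = dx)
  df <- data.frame(x = xs, height = domain$profile$h(xs))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
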