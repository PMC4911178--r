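#' Nucleus-nucleus interaction potential specification
#'
#' The contact interaction between two unit-diameter nuclei is described by a
#' piecewise-quadratic potential with three regimes in the centre-to-centre
#' distance `x` (nuclear diameters):
#' overlap (`x < 1`), where a strong harmonic repulsion
#' `k_rep * (1 - x)^2 - S` acts; an adhesive shell (`1 <= x <= 1 + R`), where
#' the well `-S * (1 - (x - 1)/R)^2` holds contacting nuclei together with
#' "stickiness" `S`; and no interaction beyond `1 + R`. The potential is
#' continuous everywhere; its derivative has a kink at contact (`x = 1`),
#' which is acceptable because only the three force regimes matter.
#'
#' @param repulsion_stiffness Harmonic stiffness of the overlap repulsion
#'   (energy per squared nuclear diameter). Must be positive. The default 100
#'   dominates adhesive strengths of order 1 so that nuclei behave as nearly
#'   hard discs.
#' @param adhesion_strength Adhesive well depth `S` (energy units), `>= 0`.
#' @param shell_width Width `R` of the adhesive shell beyond contact, in
#'   nuclear diameters. Default 0.05.
#' @return An object of class `potential_spec`.
#' @examples
#' sp <- potential_spec(adhesion_strength = 1)
#' pair_potential(1, sp)        # -S at contact
#' pair_force(1.025, sp)        # attractive inside the shell
#' @export
potential_spec <- function(repulsion_stiffness = 100,
                           adhesion_strength = 1,
                           shell_width = 0.05) {
  stopifnot(is.numeric(repulsion_stiffness), length(repulsion_stiffness) == 1,
            repulsion_stiffness > 0,
            is.numeric(adhesion_strength), length(adhesion_strength) == 1,
            adhesion_strength >= 0,
            is.numeric(shell_width), length(shell_width) == 1,
            shell_width > 0)
  structure(list(repulsion_stiffness = repulsion_stiffness,
                 adhesion_strength = adhesion_strength,
                 shell_width = shell_width),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("Pair potential: k_rep =", x$repulsion_stiffness,
      " S =", x$adhesion_strength, " R =", x$shell_width, "\n")
  invisible(x)
}

#' Pairwise interaction potential
#'
#' Evaluates the contact potential between two nuclei at centre-to-centre
#' distance `separation` (nuclear diameters). Vectorised over `separation`.
#'
#' @param separation Positive centre-to-centre distance(s), nuclear diameters.
#' @param spec A [potential_spec()].
#' @return Energy value(s); exactly 0 for `separation >= 1 + R`.
#' @export
pair_potential <- function(separation, spec = potential_spec()) {
  stopifnot(inherits(spec, "potential_spec"), is.numeric(separation))
  if (any(!is.finite(separation)) || any(separation <= 0))
    stop("separation must be positive and finite")
  k <- spec$repulsion_stiffness
  S <- spec$adhesion_strength
  R <- spec$shell_width
  v <- numeric(length(separation))
  core <- separation < 1
  shell <- separation >= 1 & separation < 1 + R  # exactly 0 from 1+R on
  v[core] <- k * (1 - separation[core])^2 - S
  v[shell] <- -S * (1 - (separation[shell] - 1) / R)^2
  v
}

#' Pairwise radial force
#'
#' Signed radial force `-dV/dx` between two nuclei; positive values push the
#' nuclei apart (repulsion, overlap regime), negative values pull them
#' together (adhesion, inside the shell). Vectorised over `separation`.
#'
#' @inheritParams pair_potential
#' @return Signed force value(s); exactly 0 for `separation >= 1 + R`.
#' @export
pair_force <- function(separation, spec = potential_spec()) {
  stopifnot(inherits(spec, "potential_spec"), is.numeric(separation))
  if (any(!is.finite(separation)) || any(separation <= 0))
    stop("separation must be positive and finite")
  k <- spec$repulsion_stiffness
  S <- spec$adhesion_strength
  R <- spec$shell_width
  f <- numeric(length(separation))
  core <- separation < 1
  shell <- separation >= 1 & separation < 1 + R
  f[core] <- 2 * k * (1 - separation[core])
  f[shell] <- -(2 * S / R) * (1 - (separation[shell] - 1) / R)
  f
}

#' Membrane contact force on a nucleus
#'
#' Force exerted on a nucleus centre by the confining membranes of a
#' [syncytium_domain()]: the flat lower boundary `y = 0`, the corrugated upper
#' boundary `y = T + A h(x)`, and the end walls `x = 0`, `x = L`. Whenever the
#' clearance between the centre and a boundary falls below the nuclear radius
#' 0.5, a harmonic repulsion of stiffness `repulsion_stiffness` acts along the
#' inward direction. Clearance to the upper boundary is measured vertically, a
#' documented approximation that is accurate because the profile varies by at
#' most ~0.75 diameters over a 250-diameter domain.
#'
#' @param centre Numeric length-2 vector `(x, y)`, nuclear diameters.
#' @param domain A [syncytium_domain()].
#' @param spec A [potential_spec()]; only the stiffness is used.
#' @return Numeric length-2 force vector.
#' @export
membrane_force <- function(centre, domain, spec = potential_spec()) {
  stopifnot(inherits(domain, "syncytium_domain"),
            is.numeric(centre), length(centre) == 2, all(is.finite(centre)))
  k <- spec$repulsion_stiffness
  x <- centre[1]; y <- centre[2]
  fx <- 0; fy <- 0
  if (y < 0.5) fy <- fy + k * (0.5 - y)
  top <- domain_top(domain, x)
  if (top - y < 0.5) fy <- fy - k * (0.5 - (top - y))
  if (x < 0.5) fx <- fx + k * (0.5 - x)
  if (domain$length - x < 0.5) fx <- fx - k * (0.5 - (domain$length - x))
  c(fx, fy)
}
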