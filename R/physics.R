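#' Medium (carrier fluid) specification
#'
#' The middle ear and a patent Eustachian tube are air-filled, so the default
#' medium is body-temperature air; a watery-fluid preset is provided for
#' sensitivity studies of a mucus-lined tube. The mean free path is used only
#' by the Cunningham slip correction and is irrelevant (zero) for liquids.
#'
#' @param name Label for reports.
#' @param temperature Absolute temperature in K (default 310, body
#'   temperature).
#' @param dynamic_viscosity Dynamic viscosity in Pa s (default 1.86e-5, air
#'   at 310 K).
#' @param mean_free_path Gas mean free path in m (default 6.8e-8, air).
#' @return An object of class `etMedium`.
#' @export
medium <- function(name = "air", temperature = 310,
                   dynamic_viscosity = 1.86e-5, mean_free_path = 6.8e-8) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("medium 'temperature' must be positive", call. = FALSE)
  if (!is.numeric(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("medium 'dynamic_viscosity' must be positive", call. = FALSE)
  if (!is.numeric(mean_free_path) || mean_free_path < 0)
    stop("medium 'mean_free_path' must be non-negative", call. = FALSE)
  structure(list(name = name, temperature = temperature,
                 dynamic_viscosity = dynamic_viscosity,
                 mean_free_path = mean_free_path),
            class = "etMedium")
}

#' @rdname medium
#' @export
mediumAir <- function() medium()

#' @rdname medium
#' @export
mediumWater <- function()
  medium(name = "water", dynamic_viscosity = 6.9e-4, mean_free_path = 0)

#' Particle specification
#'
#' @param diameter Particle diameter in nm (the standard sweep uses 20, 200
#'   and 2000 nm; 200 nm is the reference size).
#' @param density Material density in kg/m^3 (default 2000, a silica-shelled
#'   magnetite composite).
#' @param charge Dimensionless surface-charge multiplier `q >= 0` of the
#'   reference charge; the pair-interaction coefficient carries the physical
#'   units (see [interactionSpec()]).
#' @param count Number of particles in the ensemble.
#' @return An object of class `etParticleSpec`.
#' @export
particleSpec <- function(diameter = 200, density = 2000, charge = 0,
                         count = 1000L) {
  if (!is.numeric(diameter) || diameter <= 0)
    stop("particle 'diameter' must be positive", call. = FALSE)
  if (!is.numeric(density) || density < 0)
    stop("particle 'density' must be non-negative", call. = FALSE)
  if (!is.numeric(charge) || charge < 0)
    stop("particle 'charge' must be non-negative", call. = FALSE)
  count <- as.integer(count)
  if (is.na(count) || count < 1L)
    stop("particle 'count' must be a positive integer", call. = FALSE)
  structure(list(diameter = diameter, density = density, charge = charge,
                 count = count),
            class = "etParticleSpec")
}

#' External force specification
#'
#' A constant axial force models the net external pull on the particles —
#' gravity with the contralateral ear positioned downhill, or a magnetic
#' gradient force on magnetite particles. `magnitude_model = "gravity"`
#' derives the magnitude from the particle weight (buoyancy neglected);
#' `"explicit"` uses `magnitude` directly. `force_scale` is the single
#' calibratable multiplier of the force family.
#'
#' @param mode `"none"` (default) or `"constant"`.
#' @param direction `"+x"` (toward the contralateral ear) or `"-x"`.
#' @param magnitude_model `"gravity"` or `"explicit"`.
#' @param magnitude Force magnitude in N when `magnitude_model = "explicit"`.
#' @param force_scale Dimensionless multiplier (default 1).
#' @return An object of class `etForceSpec`.
#' @export
forceSpec <- function(mode = c("none", "constant"),
                      direction = c("+x", "-x"),
                      magnitude_model = c("gravity", "explicit"),
                      magnitude = 0, force_scale = 1) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  magnitude_model <- match.arg(magnitude_model)
  if (!is.numeric(magnitude) || magnitude < 0)
    stop("force 'magnitude' must be non-negative", call. = FALSE)
  if (!is.numeric(force_scale) || force_scale < 0)
    stop("force 'force_scale' must be non-negative", call. = FALSE)
  structure(list(mode = mode, direction = direction,
                 magnitude_model = magnitude_model, magnitude = magnitude,
                 force_scale = force_scale),
            class = "etForceSpec")
}

#' Pairwise electrostatic interaction specification
#'
#' Charged particles repel through a softened Coulomb kernel
#' `F = k q_i q_j d / (|d|^2 + s^2)^(3/2)` truncated at `cutoff`. The
#' reference coefficient `strength` (`k`, energy times length per unit
#' squared charge multiplier) is the single calibratable scalar of the
#' charge family; the softening length `s` removes the contact singularity.
#'
#' @param enabled Logical; when `FALSE` no pair forces are computed.
#' @param strength Reference coefficient k in N m^2 per q^2 (default 1e-25,
#'   an order-of-magnitude starting point that calibration refines).
#' @param cutoff Interaction range in mm (default 0.2).
#' @param softening Softening length in mm (default 0.005).
#' @return An object of class `etInteractionSpec`.
#' @export
interactionSpec <- function(enabled = FALSE, strength = 1e-25,
                            cutoff = 0.2, softening = 0.005) {
  if (!is.numeric(strength) || strength < 0)
    stop("interaction 'strength' must be non-negative", call. = FALSE)
  if (!is.numeric(cutoff) || !is.numeric(softening) ||
      softening < 0 || cutoff <= softening)
    stop("interaction requires cutoff > softening >= 0", call. = FALSE)
  structure(list(enabled = isTRUE(enabled), strength = strength,
                 cutoff = cutoff, softening = softening),
            class = "etInteractionSpec")
}

#' Cunningham slip correction factor
#'
#' For particles not much larger than the gas mean free path, Stokes drag
#' overestimates friction; the Cunningham factor
#' `Cc = 1 + Kn (1.257 + 0.4 exp(-1.1/Kn))` with Knudsen number
#' `Kn = mean_free_path / radius` corrects it. `Cc -> 1` in the continuum
#' limit and grows monotonically as particles shrink.
#'
#' @param radius Particle radius in m.
#' @param mean_free_path Gas mean free path in m.
#' @return Dimensionless factor `Cc >= 1`.
#' @export
slipCorrection <- function(radius, mean_free_path) {
  if (any(!is.numeric(radius)) || any(radius <= 0))
    stop("slipCorrection: 'radius' must be positive", call. = FALSE)
  if (any(mean_free_path < 0))
    stop("slipCorrection: 'mean_free_path' must be non-negative",
         call. = FALSE)
  kn <- mean_free_path / radius
  ifelse(kn == 0, 1, 1 + kn * (1.257 + 0.4 * exp(-1.1 / kn)))
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB T Cc / (6 pi eta r)`, with the Cunningham factor `Cc = 1` when
#' `slip = FALSE`. Strictly decreasing in radius.
#'
#' @param spec An [particleSpec()] object.
#' @param medium An [medium()] object.
#' @param slip Apply the Cunningham slip correction (default `TRUE`; only
#'   meaningful for gaseous media).
#' @return Diffusion coefficient in m^2/s.
#' @export
diffusionCoefficient <- function(spec, medium, slip = TRUE) {
  r <- spec$diameter * 1e-9 / 2
  cc <- if (slip) slipCorrection(r, medium$mean_free_path) else 1
  .kB * medium$temperature * cc /
    (6 * pi * medium$dynamic_viscosity * r)
}

#' Stokes mobility
#'
#' `mu = Cc / (6 pi eta r)`; satisfies the Einstein relation
#' `mu = D / (kB T)` exactly against [diffusionCoefficient()].
#'
#' @inheritParams diffusionCoefficient
#' @return Mobility in m/(s N).
#' @export
mobility <- function(spec, medium, slip = TRUE) {
  r <- spec$diameter * 1e-9 / 2
  cc <- if (slip) slipCorrection(r, medium$mean_free_path) else 1
  cc / (6 * pi * medium$dynamic_viscosity * r)
}

#' Gravity-derived force magnitude
#'
#' Particle weight `F = (4/3) pi r^3 rho g`, buoyancy neglected (particle
#' density far exceeds that of air).
#'
#' @param spec An [particleSpec()] object.
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @return Force magnitude in N.
#' @export
gravityForce <- function(spec, g = 9.81) {
  r <- spec$diameter * 1e-9 / 2
  (4 / 3) * pi * r^3 * spec$density * g
}

#' Softened pairwise Coulomb force
#'
#' Force on particle i from particle j:
#' `F = k q_i q_j delta / (|delta|^2 + s^2)^(3/2)` for separations up to the
#' cutoff, zero beyond; antisymmetric under exchange of i and j, so the
#' interaction conserves total momentum.
#'
#' @param delta `position_i - position_j`, length-3 vector in m.
#' @param q_i,q_j Dimensionless charge multipliers.
#' @param interaction An [interactionSpec()] object.
#' @return Length-3 force vector in N acting on particle i.
#' @export
pairForce <- function(delta, q_i, q_j, interaction) {
  stopifnot(length(delta) == 3)
  d2 <- sum(delta^2)
  cut <- interaction$cutoff * 1e-3
  if (d2 > cut^2 || q_i == 0 || q_j == 0) return(c(0, 0, 0))
  s2 <- (interaction$softening * 1e-3)^2
  interaction$strength * q_i * q_j * delta / (d2 + s2)^1.5
}

# signed axial external force in N (0 when mode is "none")
.externalForceX <- function(force, particles) {
  if (force$mode == "none") return(0)
  mag <- if (force$magnitude_model == "gravity")
    gravityForce(particles) else force$magnitude
  sgn <- if (force$direction == "+x") 1 else -1
  sgn * force$force_scale * mag
}
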