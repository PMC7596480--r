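#' Full simulation configuration
#'
#' Bundles geometry, medium, particle, force and interaction specifications
#' with the time grid and seed. When `dt` is `NULL` the engine chooses it
#' automatically: the diffusive step obeys `sqrt(2 D dt) <= tube_radius / 5`
#' (so wall reflections see locally flat walls) and the drift from the
#' external force is held below the same length. The deterministic
#' displacement from stiff pairwise forces is limited per particle to the
#' same cap (a trust region over the softened Coulomb kernel) rather than
#' by shrinking the global step. Non-interacting ensembles additionally
#' take coarser steps in the cavity interior, where the nearest geometric
#' feature that must be resolved is far away (see [runSimulation()]).
#'
#' @param geometry An [etGeometry()] object.
#' @param medium An [medium()] object.
#' @param particles An [particleSpec()] object.
#' @param force An [forceSpec()] object.
#' @param interaction An [interactionSpec()] object.
#' @param dt Time step in s, or `NULL` for the automatic rule.
#' @param t_end Simulation horizon in s (default 10800 s = 180 min).
#' @param record_every Recording interval in s (default 60).
#' @param seed Integer RNG seed; identical configurations reproduce outputs
#'   bit for bit.
#' @param slip Apply the Cunningham slip correction (default `TRUE`).
#' @param d_scale Global multiplier applied to both the diffusion
#'   coefficient and the mobility (they stay tied by the Einstein relation);
#'   the single calibratable scalar of the diffusion family (default 1).
#' @param source An optional source specification, see
#'   [sampleInitialEnsemble()]; defaults to the standard 0.05 mm loading
#'   slab.
#' @return An object of class `etSimulationConfig`.
#' @export
simulationConfig <- function(geometry = etGeometry(),
                             medium = mediumAir(),
                             particles = particleSpec(),
                             force = forceSpec(),
                             interaction = interactionSpec(),
                             dt = NULL, t_end = 10800, record_every = 60,
                             seed = 1L, slip = TRUE, d_scale = 1,
                             source = sourceSpec()) {
  stopifnot(inherits(geometry, "etGeometry"), inherits(medium, "etMedium"),
            inherits(particles, "etParticleSpec"),
            inherits(force, "etForceSpec"),
            inherits(interaction, "etInteractionSpec"),
            inherits(source, "etSourceSpec"))
  if (!is.numeric(t_end) || t_end < 0)
    stop("config 't_end' must be non-negative", call. = FALSE)
  if (!is.numeric(record_every) || record_every <= 0)
    stop("config 'record_every' must be positive", call. = FALSE)
  if (!is.null(dt)) {
    if (!is.numeric(dt) || dt <= 0)
      stop("config 'dt' must be positive (or NULL for the auto rule)",
           call. = FALSE)
    if (t_end > 0 && dt > record_every)
      stop("config requires dt <= record_every", call. = FALSE)
  }
  if (t_end > 0 && record_every > t_end)
    stop("config requires record_every <= t_end", call. = FALSE)
  if (!is.numeric(d_scale) || d_scale <= 0)
    stop("config 'd_scale' must be positive", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("config 'seed' must be an integer", call. = FALSE)
  if (source$slab_depth >= geometry$tube_length)
    stop("source 'slab_depth' must be smaller than the tube length",
         call. = FALSE)
  structure(list(geometry = geometry, medium = medium, particles = particles,
                 force = force, interaction = interaction, dt = dt,
                 t_end = t_end, record_every = record_every, seed = seed,
                 slip = isTRUE(slip), d_scale = d_scale, source = source),
            class = "etSimulationConfig")
}

#' @export
print.etSimulationConfig <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  particles: %d x %.4g nm, charge %.3g, density %.4g kg/m^3\n",
              x$particles$count, x$particles$diameter, x$particles$charge,
              x$particles$density))
  cat(sprintf("  medium: %s (T = %.4g K, eta = %.3g Pa s), slip %s, d_scale %.4g\n",
              x$medium$name, x$medium$temperature,
              x$medium$dynamic_viscosity, if (x$slip) "on" else "off",
              x$d_scale))
  f <- x$force
  cat(sprintf("  force: %s%s\n", f$mode,
              if (f$mode == "constant")
                sprintf(" (%s, %s, scale %.4g)", f$direction,
                        f$magnitude_model, f$force_scale) else ""))
  cat(sprintf("  interaction: %s (k = %.3g, cutoff %.3g mm)\n",
              if (x$interaction$enabled) "on" else "off",
              x$interaction$strength, x$interaction$cutoff))
  cat(sprintf("  time: t_end = %.4g s, record_every = %.4g s, dt = %s, seed = %d\n",
              x$t_end, x$record_every,
              if (is.null(x$dt)) "auto" else format(x$dt), x$seed))
  print(x$geometry)
  invisible(x)
}

# effective transport coefficients in SI units; d_scale multiplies D and mu
# together so the Einstein relation is preserved
.transport <- function(config) {
  D <- config$d_scale *
    diffusionCoefficient(config$particles, config$medium, config$slip)
  mu <- config$d_scale * mobility(config$particles, config$medium,
                                  config$slip)
  list(D = D, mu = mu,
       f_ext_x = .externalForceX(config$force, config$particles))
}

# diffusion-rule time step: sqrt(2 D dt) <= tube_radius / 5
.autoTimeStep <- function(config, D) {
  step_cap <- config$geometry$tube_radius * 1e-3 / 5
  if (D <= 0) return(config$record_every)
  min(config$record_every, step_cap^2 / (2 * D))
}
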