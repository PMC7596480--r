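#' Particle source specification
#'
#' The injected bolus is modelled as particles distributed uniformly over a
#' thin cylindrical slab at the ipsilateral tube entrance (depth
#' `slab_depth` along x, full tube cross-section). A slab rather than a
#' point source reflects a finite injected volume and keeps the matched 1-D
#' oracle initial condition non-singular.
#'
#' @param slab_depth Slab depth in mm (default 0.05); must be smaller than
#'   the tube length.
#' @return An object of class `etSourceSpec`.
#' @export
sourceSpec <- function(slab_depth = 0.05) {
  if (!is.numeric(slab_depth) || slab_depth <= 0)
    stop("source 'slab_depth' must be positive", call. = FALSE)
  structure(list(region = "source_slab", slab_depth = slab_depth),
            class = "etSourceSpec")
}

#' Sample the initial particle ensemble
#'
#' Draws `spec$count` positions i.i.d. uniform over the source slab: x
#' uniform on `[0, slab_depth]`, the transverse coordinates uniform over the
#' tube disk by rejection sampling. All particles start active. Consumes
#' R's RNG stream; call `set.seed()` (or use [runSimulation()], which seeds
#' from the configuration) for reproducibility.
#'
#' @param geometry An [etGeometry()] object.
#' @param spec An [particleSpec()] object.
#' @param source An [sourceSpec()] object.
#' @param seed Optional integer seed applied before sampling.
#' @return An `etEnsembleState` at time 0: list with `time`, `positions`
#'   (N x 3 matrix, metres), `status` (`"active"`/`"absorbed"`) and
#'   `absorption_time` (s, `NA` while active).
#' @export
sampleInitialEnsemble <- function(geometry, spec, source = sourceSpec(),
                                  seed = NULL) {
  if (source$slab_depth >= geometry$tube_length)
    stop("source 'slab_depth' must be smaller than the tube length",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$count
  R <- geometry$tube_radius * 1e-3
  x <- runif(n, 0, source$slab_depth * 1e-3)
  y <- numeric(n); z <- numeric(n)
  need <- seq_len(n)
  while (length(need)) { # rejection sampling in the disk
    yy <- runif(length(need), -R, R)
    zz <- runif(length(need), -R, R)
    ok <- yy * yy + zz * zz <= R * R
    y[need[ok]] <- yy[ok]
    z[need[ok]] <- zz[ok]
    need <- need[!ok]
  }
  ensembleState(0, cbind(x = x, y = y, z = z),
                rep("active", n), rep(NA_real_, n))
}

# constructor + invariant checks for the ensemble container
ensembleState <- function(time, positions, status, absorption_time) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            length(status) == nrow(positions),
            length(absorption_time) == nrow(positions),
            all(status %in% c("active", "absorbed")))
  active <- status == "active"
  stopifnot(all(is.na(absorption_time[active])),
            all(absorption_time[!active] <= time + 1e-9))
  structure(list(time = time, positions = positions, status = status,
                 absorption_time = absorption_time),
            class = "etEnsembleState")
}

#' @export
print.etEnsembleState <- function(x, ...) {
  n <- nrow(x$positions)
  nabs <- sum(x$status == "absorbed")
  cat(sprintf("Particle ensemble at t = %.4g s: %d particles, %d absorbed (%.1f%%)\n",
              x$time, n, nabs, 100 * nabs / n))
  invisible(x)
}

#' Miniature configurations for fast checks
#'
#' Returns a named set of small, quick-running configurations (reduced
#' particle counts and shortened horizons, each well under five seconds on
#' one CPU) covering the three behaviours worth exercising cheaply:
#' `oracle` — a straight-channel run whose axial marginal is exactly the
#' 1-D drift-diffusion process; `force_ordering` — the two-tube geometry
#' under a strong constant axial force; `zero_charge` — interactions
#' enabled with zero charge, which must match the interactions-off
#' baseline bit for bit. The same configurations ship as plain-text config
#' files under `inst/extdata/fixtures/`.
#'
#' @return Named list of `etSimulationConfig` objects.
#' @export
makeFixtureConfigs <- function() {
  list(
    oracle = simulationConfig(
      geometry = etGeometry("straight_channel"),
      particles = particleSpec(count = 200),
      t_end = 600, record_every = 60, seed = 11L),
    force_ordering = simulationConfig(
      particles = particleSpec(count = 150),
      force = forceSpec("constant", "+x", "gravity", force_scale = 0.5),
      t_end = 600, record_every = 60, seed = 12L),
    zero_charge = simulationConfig(
      particles = particleSpec(count = 64, charge = 0),
      interaction = interactionSpec(enabled = TRUE),
      t_end = 300, record_every = 60, seed = 13L)
  )
}
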