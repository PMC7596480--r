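# arrival-curve container
arrivalCurve <- function(times, n_absorbed, n_total) {
  fraction <- n_absorbed / n_total
  stopifnot(!is.unsorted(times), all(diff(fraction) >= 0),
            all(fraction >= 0 & fraction <= 1))
  structure(list(times = times, fraction = fraction,
                 n_absorbed = n_absorbed, n_total = n_total),
            class = "etArrivalCurve")
}

#' @export
print.etArrivalCurve <- function(x, ...) {
  cat(sprintf("Arrival curve: %d time points over %.4g s, final fraction %.3f (%d/%d)\n",
              length(x$times), max(x$times), x$fraction[length(x$fraction)],
              x$n_absorbed[length(x$n_absorbed)], x$n_total))
  invisible(x)
}

#' @export
as.data.frame.etArrivalCurve <- function(x, ...) {
  data.frame(time_min = x$times / 60, fraction = x$fraction,
             n_absorbed = x$n_absorbed, n_total = x$n_total)
}

#' Cumulative arrival fraction at a time
#'
#' Step interpolation: returns the fraction at the largest recorded time not
#' exceeding `t`.
#'
#' @param curve An `etArrivalCurve` from [runSimulation()].
#' @param t Time in s; must lie within the recorded range.
#' @return Fraction in `[0, 1]`.
#' @export
arrivalFraction <- function(curve, t) {
  rng <- range(curve$times)
  if (any(t < rng[1] | t > rng[2]))
    stop("arrivalFraction: t = ", t[which(t < rng[1] | t > rng[2])[1]],
         " outside the recorded range [", rng[1], ", ", rng[2], "] s",
         call. = FALSE)
  idx <- findInterval(t, curve$times)
  curve$fraction[idx]
}

#' Run a Brownian-dynamics simulation
#'
#' Initialises the ensemble from the configured source slab, then advances
#' it with the Euler-Maruyama scheme for the overdamped Langevin equation:
#' each active particle moves by `mu F dt + sqrt(2 D dt) xi` per step
#' (`xi` a standard 3-vector normal deviate, `F` the external plus pairwise
#' force), proposed positions are wall-corrected by specular reflection, and
#' trajectories crossing the contralateral plane are absorbed with
#' `absorption_time` stamped at the end of the step. Absorbed particles
#' never move again and are excluded from pair-force sums. The cumulative
#' absorbed fraction is recorded every `record_every` seconds.
#'
#' Deterministic given `config$seed`. A warning is raised if more than 1%
#' of proposed moves hit the reflection-rejection fallback (a sign the step
#' is too large for the geometry).
#'
#' @param config An [simulationConfig()] object.
#' @param snapshots Record particle positions at every record time (for
#'   [writeXYZ()] visualisation). Default `FALSE`.
#' @return List of class `etSimulationResult` with elements `curve`
#'   (`etArrivalCurve`), `state` (final `etEnsembleState`), `config`, and a
#'   `diagnostics` list (chosen dt range, rejection rate, runtime,
#'   snapshots if requested).
#' @export
runSimulation <- function(config, snapshots = FALSE) {
  stopifnot(inherits(config, "etSimulationConfig"))
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  state <- sampleInitialEnsemble(config$geometry, config$particles,
                                 config$source)
  n <- config$particles$count

  if (config$t_end <= 0) {
    curve <- arrivalCurve(0, 0L, n)
    return(structure(list(curve = curve, state = state, config = config,
                          diagnostics = list(dt = NA_real_,
                                             rejection_rate = 0,
                                             runtime = 0)),
                     class = "etSimulationResult"))
  }

  tr <- .transport(config)
  rec <- seq(config$record_every, config$t_end, by = config$record_every)
  if (rec[length(rec)] < config$t_end) rec <- c(rec, config$t_end)
  rec_dur <- diff(c(0, rec))

  inter <- config$interaction
  kqq <- if (inter$enabled) inter$strength * config$particles$charge^2 else 0
  step_cap <- config$geometry$tube_radius * 1e-3 / 5
  dt_diff <- .autoTimeStep(config, tr$D)

  # Independent particles take per-particle adaptive steps (coarse in the
  # cavity interior, fine near the tube mouths); coupled or snapshot runs
  # step synchronously. Zero charge with interactions enabled follows the
  # same path as interactions disabled, so the two are identical bit for
  # bit under a shared seed.
  adaptive <- kqq == 0 && !isTRUE(snapshots) && is.null(config$dt) &&
    (tr$D > 0 || tr$f_ext_x != 0)
  if (adaptive) {
    res <- cpp_simulate_adaptive(state$positions,
                                 state$status == "active",
                                 state$absorption_time,
                                 .geomVec(config$geometry),
                                 tr$D, tr$mu, tr$f_ext_x,
                                 0, config$t_end, 8L)
    res$counts <- vapply(rec, function(tt)
      sum(!is.na(res$absorption_time) & res$absorption_time <= tt),
      integer(1))
  } else {
    res <- cpp_simulate(state$positions,
                        state$status == "active",
                        state$absorption_time,
                        .geomVec(config$geometry),
                        tr$D, tr$mu, tr$f_ext_x,
                        kqq, inter$cutoff * 1e-3, inter$softening * 1e-3,
                        rec_dur, 0,
                        if (is.null(config$dt)) -1 else config$dt,
                        dt_diff, step_cap,
                        8L, TRUE, isTRUE(snapshots),
                        if (kqq > 0) 1.0 else 0)
  }

  status <- ifelse(res$active, "active", "absorbed")
  final <- ensembleState(res$time, res$positions, status,
                         res$absorption_time)
  curve <- arrivalCurve(c(0, rec), c(0L, res$counts), n)
  rej_rate <- if (res$n_moves > 0) res$n_reject / res$n_moves else 0
  if (rej_rate > 0.01)
    warning(sprintf("reflection-rejection fallback rate %.2f%% exceeds 1%%; the time step is too large for the geometry",
                    100 * rej_rate), call. = FALSE)
  diagnostics <- list(dt = c(min = res$dt_min, max = res$dt_max),
                      rejection_rate = rej_rate,
                      n_moves = res$n_moves,
                      runtime = proc.time()[["elapsed"]] - t0)
  if (isTRUE(snapshots)) {
    diagnostics$snapshots <- res$snapshots
    diagnostics$snapshot_times <- rec
  }
  structure(list(curve = curve, state = final, config = config,
                 diagnostics = diagnostics),
            class = "etSimulationResult")
}

#' @export
print.etSimulationResult <- function(x, ...) {
  cat(sprintf("Brownian-dynamics run: N = %d, seed = %d\n",
              x$config$particles$count, x$config$seed))
  print(x$curve)
  invisible(x)
}

#' Advance an ensemble by one or more explicit steps
#'
#' Low-level access to the integrator used by [runSimulation()], advancing
#' an existing `etEnsembleState` by `n_steps` steps of length `dt` under the
#' physics of `config`. With `walls = FALSE` the domain is ignored (free
#' space, no absorption) — useful for checking the unconfined statistics of
#' the scheme, e.g. the mean squared displacement. Consumes R's RNG stream.
#'
#' @param state An `etEnsembleState`.
#' @param config An [simulationConfig()] object (its `dt`/`t_end` are not
#'   used here).
#' @param dt Step length in s.
#' @param n_steps Number of steps (default 1).
#' @param walls Apply wall reflection and absorption (default `TRUE`).
#' @return The advanced `etEnsembleState`.
#' @export
stepEnsemble <- function(state, config, dt, n_steps = 1L, walls = TRUE) {
  stopifnot(inherits(state, "etEnsembleState"),
            inherits(config, "etSimulationConfig"), dt > 0, n_steps >= 1)
  tr <- .transport(config)
  inter <- config$interaction
  kqq <- if (inter$enabled) inter$strength * config$particles$charge^2 else 0
  step_cap <- config$geometry$tube_radius * 1e-3 / 5
  res <- cpp_simulate(state$positions, state$status == "active",
                      state$absorption_time, .geomVec(config$geometry),
                      tr$D, tr$mu, tr$f_ext_x,
                      kqq, inter$cutoff * 1e-3, inter$softening * 1e-3,
                      rep(dt, n_steps), state$time,
                      dt, dt, step_cap, 8L, isTRUE(walls), FALSE, 0)
  ensembleState(res$time, res$positions,
                ifelse(res$active, "active", "absorbed"),
                res$absorption_time)
}
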