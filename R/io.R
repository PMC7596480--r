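# Known configuration keys, per section. Unknown keys are rejected so a
# typo cannot silently fall back to a default.
.configSchema <- list(
  geometry = c("mode", "tube_length", "tube_radius", "cavity_side"),
  medium = c("preset", "name", "temperature", "dynamic_viscosity",
             "mean_free_path"),
  particles = c("diameter", "density", "charge", "count"),
  force = c("mode", "direction", "magnitude_model", "magnitude",
            "force_scale"),
  interaction = c("enabled", "strength", "cutoff", "softening"),
  source = c("slab_depth"),
  top = c("geometry", "medium", "particles", "force", "interaction",
          "source", "dt", "t_end", "record_every", "seed", "slip",
          "d_scale")
)

#' Load a simulation configuration from a YAML file
#'
#' Reads a structured key-value (YAML) configuration, fills every missing
#' field with the standard defaults (1.5 / 0.05 / 1.0 mm geometry, 200 nm
#' particles, air at 310 K, 180 min horizon) and validates the result.
#' Unknown keys are rejected with the offending key named. The `medium`
#' section accepts `preset: air` or `preset: water` plus overrides.
#'
#' @param path Path to the configuration file.
#' @return A validated [simulationConfig()].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("config file '", path, "' must contain a key-value mapping",
         call. = FALSE)
  .checkKeys(raw, .configSchema$top, "top level", path)
  for (sec in c("geometry", "medium", "particles", "force", "interaction",
                "source")) {
    if (!is.null(raw[[sec]])) {
      if (!is.list(raw[[sec]]))
        stop("config section '", sec, "' in '", path,
             "' must be a mapping", call. = FALSE)
      .checkKeys(raw[[sec]], .configSchema[[sec]], sec, path)
    }
  }

  g <- raw$geometry %||% list()
  geometry <- do.call(etGeometry, g)

  m <- raw$medium %||% list()
  med <- switch(m$preset %||% "air",
                air = mediumAir(), water = mediumWater(),
                stop("config: unknown medium preset '", m$preset, "'",
                     call. = FALSE))
  for (f in intersect(names(m), c("name", "temperature",
                                  "dynamic_viscosity", "mean_free_path")))
    med[[f]] <- m[[f]]
  med <- do.call(medium, unclass(med))

  particles <- do.call(particleSpec, raw$particles %||% list())
  force <- do.call(forceSpec, raw$force %||% list())
  interaction <- do.call(interactionSpec, raw$interaction %||% list())
  source <- do.call(sourceSpec, raw$source %||% list())

  simulationConfig(
    geometry = geometry, medium = med, particles = particles,
    force = force, interaction = interaction,
    dt = raw$dt %||% NULL,
    t_end = raw$t_end %||% 10800,
    record_every = raw$record_every %||% 60,
    seed = raw$seed %||% 1L,
    slip = raw$slip %||% TRUE,
    d_scale = raw$d_scale %||% 1,
    source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkKeys <- function(x, allowed, where, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("config '", path, "': unknown key '", bad[1], "' in ", where,
         " (allowed: ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
}

#' Serialise a configuration back to YAML
#'
#' Inverse of [loadConfig()]: `loadConfig(dumpConfig(cfg, f))` reproduces
#' `cfg` semantically.
#'
#' @param config An [simulationConfig()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dumpConfig <- function(config, path) {
  stopifnot(inherits(config, "etSimulationConfig"))
  g <- config$geometry
  out <- list(
    geometry = list(mode = g$mode, tube_length = g$tube_length,
                    tube_radius = g$tube_radius,
                    cavity_side = g$cavity_side),
    medium = list(name = config$medium$name,
                  temperature = config$medium$temperature,
                  dynamic_viscosity = config$medium$dynamic_viscosity,
                  mean_free_path = config$medium$mean_free_path),
    particles = unclass(config$particles),
    force = unclass(config$force),
    interaction = unclass(config$interaction),
    source = list(slab_depth = config$source$slab_depth),
    t_end = config$t_end, record_every = config$record_every,
    seed = config$seed, slip = config$slip, d_scale = config$d_scale)
  if (!is.null(config$dt)) out$dt <- config$dt
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write an arrival curve as CSV
#'
#' Columns `time_min, fraction, n_absorbed, n_total`.
#'
#' @param curve An `etArrivalCurve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeArrivalCurve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read an arrival curve written by [writeArrivalCurve()]
#'
#' @param path CSV file path.
#' @return An `etArrivalCurve`.
#' @export
readArrivalCurve <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_min", "fraction", "n_absorbed", "n_total") %in%
                  names(df)))
  arrivalCurve(df$time_min * 60, df$n_absorbed, df$n_total[1])
}

#' Write a scenario table as CSV
#'
#' Header `label,diameter_nm,charge,force,fraction_180min,se,n_seeds,
#' n_particles`.
#'
#' @param table An `etScenarioTable` from [runScenarioTable()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeScenarioTable <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Build a run manifest
#'
#' Provenance record written alongside every output: the configuration
#' echo, package version, seed, chosen time-step range, rejection rate,
#' wall-clock runtime and output paths. Re-running the configuration in
#' the manifest reproduces the outputs bit for bit.
#'
#' @param result An `etSimulationResult` from [runSimulation()].
#' @param paths Named character vector of output files.
#' @return List of class `etRunManifest`.
#' @export
runManifest <- function(result, paths = character()) {
  structure(list(
    package = "eustasim",
    version = as.character(packageVersion("eustasim")),
    seed = result$config$seed,
    dt = result$diagnostics$dt,
    rejection_rate = result$diagnostics$rejection_rate,
    runtime_s = result$diagnostics$runtime,
    outputs = as.list(paths),
    config = yaml::yaml.load(yaml::as.yaml(.configAsList(result$config)))
  ), class = "etRunManifest")
}

.configAsList <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  dumpConfig(config, tmp)
  yaml::read_yaml(tmp)
}

#' Write simulation outputs with a manifest
#'
#' Writes the arrival curve (and optional scenario table) as CSV plus a
#' YAML manifest into `out_dir`. Files are written to temporaries first
#' and renamed, and the directory is checked up front, so a failure
#' cannot leave a partial set.
#'
#' @param curve An `etArrivalCurve`.
#' @param manifest An `etRunManifest` (see [runManifest()]).
#' @param out_dir Output directory (created if missing).
#' @param table Optional `etScenarioTable`.
#' @param prefix File-name prefix (default `"run"`).
#' @return Named character vector of the files written.
#' @export
writeOutputs <- function(curve, manifest, out_dir, table = NULL,
                         prefix = "run") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("writeOutputs: directory '", out_dir, "' is not writable",
         call. = FALSE)
  paths <- c(curve = file.path(out_dir, paste0(prefix, "_curve.csv")),
             manifest = file.path(out_dir, paste0(prefix, "_manifest.yaml")))
  if (!is.null(table))
    paths["table"] <- file.path(out_dir, paste0(prefix, "_table.csv"))
  tmp <- vapply(paths, function(p)
    tempfile(tmpdir = out_dir, fileext = ".tmp"), character(1))
  writeArrivalCurve(curve, tmp[["curve"]])
  if (!is.null(table)) writeScenarioTable(table, tmp[["table"]])
  manifest$outputs <- as.list(paths)
  yaml::write_yaml(unclass(manifest), tmp[["manifest"]])
  for (k in names(paths)) file.rename(tmp[[k]], paths[[k]])
  paths
}

#' Write trajectory snapshots in XYZ format
#'
#' One frame per record time, element tag `P`, coordinates in mm —
#' viewable in standard molecular viewers.
#'
#' @param result An `etSimulationResult` produced with
#'   `runSimulation(..., snapshots = TRUE)`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(result, path) {
  snaps <- result$diagnostics$snapshots
  if (is.null(snaps))
    stop("writeXYZ: run the simulation with snapshots = TRUE",
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  times <- result$diagnostics$snapshot_times
  for (i in seq_along(snaps)) {
    m <- snaps[[i]] * 1e3 # m -> mm
    writeLines(c(as.character(nrow(m)),
                 sprintf("t = %g s", times[i]),
                 sprintf("P %.6f %.6f %.6f", m[, 1], m[, 2], m[, 3])),
               con)
  }
  invisible(path)
}
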