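test_that("a minimal config file fills every standard default", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("seed: 42", f)
  cfg <- loadConfig(f)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$geometry$tube_length, 1.5)
  expect_equal(cfg$geometry$tube_radius, 0.05)
  expect_equal(cfg$geometry$cavity_side, 1.0)
  expect_equal(cfg$particles$diameter, 200)
  expect_equal(cfg$medium$name, "air")
  expect_equal(cfg$medium$temperature, 310)
  expect_equal(cfg$t_end, 10800)
  expect_true(cfg$slip)
  expect_null(cfg$dt)
})

test_that("unknown configuration keys are rejected by name", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 1", "particules:", "  diameter: 10"), f)
  expect_error(loadConfig(f), "unknown key 'particules'")
  writeLines(c("particles:", "  diamter: 10"), f)
  expect_error(loadConfig(f), "unknown key 'diamter'")
})

test_that("configurations survive a dump/load round trip", {
  cfg <- simulationConfig(
    geometry = etGeometry("straight_channel", tube_length = 2),
    medium = mediumWater(),
    particles = particleSpec(diameter = 20, charge = 0.5, count = 64L),
    force = forceSpec("constant", "-x", "explicit", magnitude = 1e-16,
                      force_scale = 0.3),
    interaction = interactionSpec(enabled = TRUE, strength = 2e-24),
    dt = 0.5, t_end = 600, record_every = 60, seed = 99L,
    slip = FALSE, d_scale = 2.5)
  f <- withr::local_tempfile(fileext = ".yaml")
  dumpConfig(cfg, f)
  expect_equal(loadConfig(f), cfg)
})

test_that("arrival curves survive a CSV round trip", {
  cfg <- simulationConfig(geometry = etGeometry("straight_channel"),
                          particles = particleSpec(count = 100),
                          t_end = 600, seed = 12L, d_scale = 60)
  cv <- runSimulation(cfg)$curve
  f <- withr::local_tempfile(fileext = ".csv")
  writeArrivalCurve(cv, f)
  cv2 <- readArrivalCurve(f)
  expect_equal(cv2$times, cv$times)
  expect_equal(cv2$fraction, cv$fraction)
  expect_equal(cv2$n_absorbed, cv$n_absorbed)
  expect_equal(cv2$n_total, cv$n_total)
  # header is the documented fixed contract
  expect_identical(readLines(f, n = 1),
                   "\"time_min\",\"fraction\",\"n_absorbed\",\"n_total\"")
})

test_that("outputs are written together with a faithful manifest", {
  cfg <- makeFixtureConfigs()$oracle
  res <- runSimulation(cfg)
  out <- withr::local_tempdir()
  paths <- writeOutputs(res$curve, runManifest(res), out)
  expect_true(all(file.exists(paths)))
  man <- yaml::read_yaml(paths[["manifest"]])
  expect_equal(man$seed, cfg$seed)
  expect_false(is.null(man$dt))
  expect_equal(man$config$particles$diameter, cfg$particles$diameter)
  # no table file when no table is given
  expect_false(any(grepl("table", list.files(out))))
  # re-running the manifest's config reproduces the curve bit for bit
  cfg2 <- simulationConfig(
    geometry = do.call(etGeometry, man$config$geometry),
    particles = do.call(particleSpec, man$config$particles),
    t_end = man$config$t_end, seed = man$config$seed)
  expect_identical(runSimulation(cfg2)$curve$fraction, res$curve$fraction)
})

test_that("XYZ snapshots are one readable frame per record time", {
  cfg <- makeFixtureConfigs()$zero_charge
  res <- runSimulation(cfg, snapshots = TRUE)
  f <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(res, f)
  lines <- readLines(f)
  n <- cfg$particles$count
  n_frames <- length(res$diagnostics$snapshots)
  expect_length(lines, n_frames * (n + 2))
  expect_identical(lines[1], as.character(n))
  expect_match(lines[3], "^P -?[0-9.]+ -?[0-9.]+ -?[0-9.]+$")
})

test_that("the command line drives a simulation end to end", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "run.yaml")
  dumpConfig(makeFixtureConfigs()$oracle, cfgfile)
  status <- suppressMessages(
    cliMain(c("simulate", "--config", cfgfile, "--seed", "5",
              "--out", out)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "run_curve.csv")))
  expect_true(file.exists(file.path(out, "run_manifest.yaml")))
  expect_equal(yaml::read_yaml(file.path(out, "run_manifest.yaml"))$seed, 5)
})

test_that("the oracle subcommand emits the series solution", {
  out <- withr::local_tempfile(fileext = ".csv")
  status <- suppressMessages(
    cliMain(c("oracle", "--D", "1.22e-10", "--v", "0", "--L", "4e-3",
              "--t-end", "10800", "--points", "7", "--out", out)))
  expect_equal(status, 0L)
  df <- read.csv(out)
  expect_named(df, c("time_s", "fraction"))
  # slab default narrow enough to track the point-source series closely
  expect_equal(df$fraction[7],
               seriesArrivalPureDiffusion(1.22e-10, 4e-3, 10800),
               tolerance = 5e-3)
})

test_that("bad CLI invocations fail loudly but cleanly", {
  expect_gt(suppressMessages(cliMain(character())), 0)
  expect_gt(suppressMessages(cliMain("frobnicate")), 0)
  expect_gt(suppressMessages(cliMain(c("simulate", "--config",
                                       "/nonexistent.yaml"))), 0)
  expect_equal(suppressMessages(cliMain("--version")), 0L)
})
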