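test_that("the standard scenario set enumerates the three sweeps", {
  scs <- standardScenarios()
  expect_length(scs, 9)
  labs <- vapply(scs, `[[`, character(1), "label")
  expect_false(anyDuplicated(labs) > 0)
  sweeps <- vapply(scs, `[[`, character(1), "sweep_variable")
  expect_equal(as.vector(table(sweeps)[c("force_direction", "size",
                                         "charge")]),
               c(3L, 3L, 3L))
  # all scenarios run to the 180 min horizon
  expect_true(all(vapply(scs, function(s) s$config$t_end, numeric(1)) ==
                    10800))
  # size-sweep configs differ only in the particle diameter
  size <- scs[vapply(scs, function(s) s$sweep_variable == "size",
                     logical(1))]
  expect_equal(sort(vapply(size, function(s) s$config$particles$diameter,
                           numeric(1))), c(20, 200, 2000))
  strip <- function(s) {
    cfg <- s$config
    cfg$particles$diameter <- NULL
    cfg
  }
  expect_equal(strip(size[[1]]), strip(size[[2]]))
  expect_equal(strip(size[[1]]), strip(size[[3]]))
  # charge-0 scenario is flagged equivalent to interactions disabled
  ch0 <- scs[[which(labs == "charge_0")]]
  expect_true(ch0$equivalent_disabled)
  expect_equal(ch0$config$particles$charge, 0)
  # charge scenarios share one interaction strength, charges 0, 0.1, 1
  charge <- scs[vapply(scs, function(s) s$sweep_variable == "charge",
                       logical(1))]
  expect_equal(sort(vapply(charge, function(s) s$config$particles$charge,
                           numeric(1))), c(0, 0.1, 1))
  ks <- vapply(charge, function(s) s$config$interaction$strength,
               numeric(1))
  expect_equal(length(unique(ks)), 1L)
  # force scenarios share one force scale with flipped sign only
  fp <- scs[[which(labs == "force_plus_x")]]$config$force
  fm <- scs[[which(labs == "force_minus_x")]]$config$force
  expect_equal(fp$force_scale, fm$force_scale)
  expect_equal(fp$direction, "+x")
  expect_equal(fm$direction, "-x")
})

test_that("scenario tables carry replicate statistics", {
  scs <- standardScenarios(n_noninteracting = 60L,
                           d_scale = 40)[c(1, 5)]
  scs[[1]]$config$t_end <- 600
  scs[[2]]$config$t_end <- 600
  scs[[2]]$label <- "baseline_bis"
  tab <- runScenarioTable(scs, n_seeds = 3L, base_seed = 9L)
  expect_s3_class(tab, "etScenarioTable")
  expect_named(tab, c("label", "diameter_nm", "charge", "force",
                      "fraction_180min", "se", "n_seeds", "n_particles"))
  expect_true(all(tab$fraction_180min >= 0 & tab$fraction_180min <= 1))
  expect_true(all(tab$n_seeds == 3L))
  expect_true(all(tab$n_particles == 60L))
  # same nominal scenario, different labels: close but independent seeds
  expect_false(identical(tab$fraction_180min[1], tab$fraction_180min[2]))
})

test_that("bisection hits a midpoint target immediately", {
  evals <- 0
  f <- function(x) { evals <<- evals + 1; x / 10 }
  res <- calibrateScalar(f, c(0, 10), target_fraction = 0.5, tol = 1e-9)
  expect_equal(res$value, 5)
  expect_lte(res$iterations, 2)
  expect_true(res$converged)
})

test_that("bisection recovers a known diffusion coefficient via the oracle", {
  D_star <- 2.3e-10
  L <- 4e-3
  target <- solveDriftDiffusion1D(D_star, 0, L, 10800, init = "slab")
  f <- function(D) solveDriftDiffusion1D(D, 0, L, 10800, init = "slab")
  res <- calibrateScalar(f, c(D_star / 10, 10 * D_star), target,
                         tol = 1e-5, max_iter = 60, scalar = "D")
  expect_lt(abs(res$value - D_star) / D_star, 0.01)
})

test_that("non-monotone responses and bad brackets raise descriptive errors", {
  # a hump: target lies between the end fractions, but the midpoint breaks
  # the monotone ordering
  expect_error(
    calibrateScalar(function(x) 4 * x * (1 - x), c(0, 0.9), 0.3,
                    scalar = "toy"),
    "not monotone")
  expect_error(
    calibrateScalar(function(x) x / 100, c(0, 1), 0.9, scalar = "toy"),
    "unattainable")
})

test_that("diffusion-scale calibration inverts the arrival curve in time", {
  # cheap check on the straight channel where the oracle gives the truth:
  # fitted scale s must satisfy F_oracle(s * D0 * t_ref) = target
  cfg <- simulationConfig(geometry = etGeometry("straight_channel"),
                          particles = particleSpec(count = 400))
  D0 <- eustasim:::.transport(cfg)$D
  target <- 0.5
  cal <- calibrateDiffusionScale(cfg, target, t_ref = 10800,
                                 horizon_factor = 12,
                                 n_particles = 800L, seed = 55L)
  expect_s3_class(cal, "etCalibrationResult")
  oracle_at_scale <- solveDriftDiffusion1D(cal$value * D0, 0, 4e-3, 10800,
                                           init = "slab")
  # binomial accuracy of the probe at N = 800
  expect_lt(abs(oracle_at_scale - target), 3 * sqrt(0.25 / 800) + 0.02)
})

test_that("shell thickness halves the diameter difference", {
  expect_equal(shellThickness(265.2, 338.5), 36.65)
  expect_equal(round(shellThickness(265.2, 338.5), 1), 36.7)
  expect_equal(shellThickness(100, 100), 0)
  expect_error(shellThickness(100, 90), "total diameter")
  expect_error(shellThickness(-1, 10), "non-negative")
})

test_that("spreading frequency reports exact binomial summaries", {
  sf <- spreadingFrequency(4, 6)
  expect_equal(sf$percent, 66.7)
  ref <- binom.test(4, 6)$conf.int
  expect_equal(sf$conf_int, as.numeric(ref))
  expect_equal(spreadingFrequency(0, 6)$percent, 0)
  expect_equal(spreadingFrequency(6, 6)$percent, 100)
  expect_error(spreadingFrequency(7, 6), "0 <= k <= n")
})
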