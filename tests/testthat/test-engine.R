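# Internal kernel access for the deterministic degenerate cases (D = 0 is
# not reachable through the physical constructors, which require positive
# temperature and viscosity).
run_kernel <- function(pos, D, mu, fx, dt, n_steps, walls) {
  geom <- eustasim:::.geomVec(etGeometry("straight_channel"))
  set.seed(1)
  eustasim:::cpp_simulate(pos, rep(TRUE, nrow(pos)),
                          rep(NA_real_, nrow(pos)), geom,
                          D, mu, fx, 0, 2e-4, 5e-6,
                          rep(dt, n_steps), 0, dt, dt, 1e-5,
                          8L, walls, FALSE, 0)
}

test_that("with no diffusion and no force nothing moves", {
  pos <- cbind(runif(20, 0, 0.004), 0, 0)
  res <- run_kernel(pos, 0, 1e10, 0, 1, 5, walls = TRUE)
  expect_equal(res$positions, pos)
  expect_true(all(res$active))
})

test_that("pure drift advances exactly mu F dt per step", {
  pos <- cbind(rep(1e-3, 10), 0, 0)
  mu <- 2.85e10; fx <- 1e-16; dt <- 0.5
  res <- run_kernel(pos, 0, mu, fx, dt, 7, walls = FALSE)
  expect_equal(res$positions[, 1], pos[, 1] + 7 * mu * fx * dt,
               tolerance = 1e-12)
  expect_equal(res$positions[, 2], pos[, 2])
})

test_that("free-space ensemble MSD matches 6 D t", {
  cfg <- simulationConfig(particles = particleSpec(count = 10000))
  set.seed(42)
  st <- sampleInitialEnsemble(cfg$geometry, cfg$particles, cfg$source)
  D <- eustasim:::.transport(cfg)$D
  st2 <- stepEnsemble(st, cfg, dt = 0.01, n_steps = 100, walls = FALSE)
  disp <- st2$positions - st$positions
  msd <- mean(rowSums(disp^2))
  t <- 1
  # SE of the MSD estimator: |X|^2/(2Dt) is chi^2_3, so var = 24 (Dt)^2 / N
  se <- sqrt(24 / 10000) * 2 * D * t
  expect_lt(abs(msd - 6 * D * t), 3 * se)
})

test_that("a zero-length run yields a single-point zero curve", {
  res <- runSimulation(simulationConfig(
    particles = particleSpec(count = 10), t_end = 0))
  expect_equal(res$curve$times, 0)
  expect_equal(res$curve$fraction, 0)
})

test_that("identical configurations reproduce results bit for bit", {
  cfg <- simulationConfig(geometry = etGeometry("straight_channel"),
                          particles = particleSpec(count = 200),
                          t_end = 600, seed = 31L, d_scale = 50)
  r1 <- runSimulation(cfg)
  r2 <- runSimulation(cfg)
  expect_identical(r1$curve$fraction, r2$curve$fraction)
  expect_identical(r1$state$positions, r2$state$positions)
  expect_identical(r1$state$absorption_time, r2$state$absorption_time)
  cfg$seed <- 32L
  r3 <- runSimulation(cfg)
  expect_false(identical(r1$state$positions, r3$state$positions))
})

test_that("particle number is conserved and the curve is monotone in [0,1]", {
  cfg <- simulationConfig(geometry = etGeometry("straight_channel"),
                          particles = particleSpec(count = 300),
                          t_end = 1200, seed = 33L, d_scale = 50)
  res <- runSimulation(cfg)
  st <- res$state
  expect_equal(sum(st$status == "active") + sum(st$status == "absorbed"),
               300L)
  expect_gt(sum(st$status == "absorbed"), 0) # something actually arrives
  expect_true(all(diff(res$curve$fraction) >= 0))
  expect_true(all(res$curve$fraction >= 0 & res$curve$fraction <= 1))
  expect_equal(res$curve$fraction[1], 0)
  # active particles are inside the domain, in mm coordinates
  act <- st$positions[st$status == "active", , drop = FALSE] * 1e3
  expect_true(all(geomContains(cfg$geometry, act)))
  # absorbed particles sit on the absorbing plane with a stamped time
  ab <- st$status == "absorbed"
  expect_true(all(abs(st$positions[ab, 1] * 1e3 - 4.0) < 1e-9))
  expect_true(all(st$absorption_time[ab] <= 1200))
})

test_that("absorbed particles never move and their times are never revised", {
  cfg <- simulationConfig(geometry = etGeometry("straight_channel"),
                          particles = particleSpec(count = 300),
                          seed = 34L, d_scale = 50)
  set.seed(cfg$seed)
  st <- sampleInitialEnsemble(cfg$geometry, cfg$particles, cfg$source)
  st <- stepEnsemble(st, cfg, dt = 0.2, n_steps = 3000)
  ab1 <- st$status == "absorbed"
  expect_gt(sum(ab1), 0)
  pos1 <- st$positions[ab1, , drop = FALSE]
  t1 <- st$absorption_time[ab1]
  st2 <- stepEnsemble(st, cfg, dt = 0.2, n_steps = 2000)
  expect_identical(st2$positions[ab1, , drop = FALSE], pos1)
  expect_identical(st2$absorption_time[ab1], t1)
  # conservation still holds after more absorption
  expect_equal(sum(st2$status == "active") + sum(st2$status == "absorbed"),
               300L)
})

test_that("arrivalFraction steps through the recorded grid", {
  cfg <- simulationConfig(geometry = etGeometry("straight_channel"),
                          particles = particleSpec(count = 200),
                          t_end = 600, seed = 35L, d_scale = 80)
  res <- runSimulation(cfg)
  cv <- res$curve
  expect_equal(arrivalFraction(cv, 0), 0)
  expect_equal(arrivalFraction(cv, 600), cv$fraction[length(cv$fraction)])
  # step interpolation uses the latest record at or before t
  expect_equal(arrivalFraction(cv, 119), arrivalFraction(cv, 60))
  expect_lte(arrivalFraction(cv, 60), arrivalFraction(cv, 300))
  expect_error(arrivalFraction(cv, 601), "outside the recorded range")
  expect_error(arrivalFraction(cv, -1), "outside the recorded range")
})

test_that("zero charge with interactions on equals interactions off exactly", {
  fx <- makeFixtureConfigs()
  cfg_on <- fx$zero_charge
  cfg_off <- cfg_on
  cfg_off$interaction <- interactionSpec(enabled = FALSE)
  r_on <- runSimulation(cfg_on)
  r_off <- runSimulation(cfg_off)
  expect_identical(r_on$state$positions, r_off$state$positions)
  expect_identical(r_on$curve$fraction, r_off$curve$fraction)
})

test_that("charged ensembles spread faster than neutral ones", {
  # strong repulsion in the synchronous kernel pushes the bolus apart
  base <- simulationConfig(particles = particleSpec(count = 48, charge = 1),
                           interaction = interactionSpec(enabled = TRUE,
                                                         strength = 1e-23),
                           t_end = 120, seed = 36L)
  neutral <- base
  neutral$particles$charge <- 0
  spread <- function(res) mean(res$state$positions[, 1])
  expect_gt(spread(runSimulation(base)), spread(runSimulation(neutral)))
})
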