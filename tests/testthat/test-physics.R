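test_that("slip correction reduces to the continuum limit and is monotone", {
  expect_equal(slipCorrection(1e-7, 0), 1)
  # Kn = 0.68: hand evaluation of the Cunningham formula
  expect_equal(slipCorrection(1e-7, 6.8e-8), 1.9087, tolerance = 1e-4)
  radii <- 10^seq(-8.5, -5, length.out = 40)
  cc <- slipCorrection(radii, 6.8e-8)
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc >= 1))
  expect_error(slipCorrection(0, 6.8e-8), "positive")
})

test_that("diffusion coefficient follows Stokes-Einstein", {
  m <- mediumAir()
  p100 <- particleSpec(diameter = 200) # radius 100 nm
  # direct formula evaluation, kB = 1.380649e-23, T = 310, eta = 1.86e-5
  expect_equal(diffusionCoefficient(p100, m, slip = FALSE), 1.2208e-10,
               tolerance = 1e-4)
  # 1/r scaling without slip
  expect_equal(diffusionCoefficient(particleSpec(400), m, slip = FALSE) * 2,
               diffusionCoefficient(p100, m, slip = FALSE))
  expect_equal(diffusionCoefficient(particleSpec(20), m, slip = FALSE) /
                 diffusionCoefficient(p100, m, slip = FALSE), 10)
  # D * r constant across the standard sizes (pure Stokes-Einstein)
  Dr <- vapply(c(20, 200, 2000), function(d)
    diffusionCoefficient(particleSpec(d), m, slip = FALSE) * d,
    numeric(1))
  expect_equal(max(Dr) / min(Dr), 1, tolerance = 1e-12)
  # slip only ever increases D, more so for small particles
  expect_gt(diffusionCoefficient(particleSpec(20), m, TRUE) /
              diffusionCoefficient(particleSpec(20), m, FALSE),
            diffusionCoefficient(p100, m, TRUE) /
              diffusionCoefficient(p100, m, FALSE))
})

test_that("mobility satisfies the Einstein relation to machine precision", {
  for (d in c(20, 137, 200, 2000)) {
    for (med in list(mediumAir(), mediumWater())) {
      for (slip in c(TRUE, FALSE)) {
        p <- particleSpec(d)
        expect_equal(
          mobility(p, med, slip) * 1.380649e-23 * med$temperature,
          diffusionCoefficient(p, med, slip),
          tolerance = 1e-12)
      }
    }
  }
  # direct evaluation at r = 100 nm, air, no slip
  expect_equal(mobility(particleSpec(200), mediumAir(), slip = FALSE),
               1 / (6 * pi * 1.86e-5 * 1e-7), tolerance = 1e-12)
  radii <- c(20, 200, 2000)
  mu <- vapply(radii, function(d)
    mobility(particleSpec(d), mediumAir(), TRUE), numeric(1))
  expect_true(all(diff(mu) < 0))
})

test_that("gravity-derived force scales with the particle volume", {
  expect_equal(gravityForce(particleSpec(200, density = 0)), 0)
  # hand evaluation: (4/3) pi (1e-7)^3 * 2000 * 9.81
  expect_equal(gravityForce(particleSpec(200, density = 2000)), 8.218e-17,
               tolerance = 1e-4)
  expect_equal(gravityForce(particleSpec(2000)) /
                 gravityForce(particleSpec(200)), 1000, tolerance = 1e-12)
})

test_that("softened pair force is repulsive, truncated and antisymmetric", {
  ia <- interactionSpec(enabled = TRUE, strength = 1e-24,
                        cutoff = 0.2, softening = 0.005)
  expect_equal(pairForce(c(1e-5, 0, 0), 0, 1, ia), c(0, 0, 0))
  # hand evaluation of the softened kernel at |delta| = 0.01 mm
  f <- pairForce(c(1e-5, 0, 0), 1, 1, ia)
  expect_equal(f[1], 1e-24 * 1e-5 / ((1e-5)^2 + (5e-6)^2)^1.5,
               tolerance = 1e-12)
  expect_gt(f[1], 0) # repulsive along +delta
  # zero beyond the cutoff
  expect_equal(pairForce(c(2.001e-4, 0, 0), 1, 1, ia), c(0, 0, 0))
  # antisymmetry under particle exchange
  set.seed(5)
  for (i in 1:50) {
    d <- runif(3, -1e-4, 1e-4)
    q <- runif(2, 0, 2)
    expect_equal(pairForce(d, q[1], q[2], ia),
                 -pairForce(-d, q[2], q[1], ia))
  }
})

test_that("pairwise interaction forces sum to zero over an ensemble", {
  ia <- interactionSpec(enabled = TRUE, strength = 1e-24)
  set.seed(6)
  n <- 25
  pos <- matrix(runif(3 * n, -1e-4, 1e-4), ncol = 3)
  q <- runif(n, 0, 1)
  total <- c(0, 0, 0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    total <- total + pairForce(d, q[i], q[j], ia) +
      pairForce(-d, q[j], q[i], ia)
  }
  expect_equal(total, c(0, 0, 0), tolerance = 1e-30)
})

test_that("specification constructors validate their inputs", {
  expect_error(particleSpec(diameter = -1), "diameter")
  expect_error(particleSpec(count = 0), "count")
  expect_error(particleSpec(charge = -0.1), "charge")
  expect_error(medium(temperature = 0), "temperature")
  expect_error(interactionSpec(cutoff = 0.001, softening = 0.005),
               "cutoff > softening")
  expect_error(forceSpec(magnitude = -1), "magnitude")
  # force mode none means zero force regardless of the other fields
  f <- forceSpec("none", "+x", "explicit", magnitude = 1)
  expect_equal(eustasim:::.externalForceX(f, particleSpec()), 0)
  fg <- forceSpec("constant", "-x", "gravity", force_scale = 0.5)
  expect_equal(eustasim:::.externalForceX(fg, particleSpec()),
               -0.5 * gravityForce(particleSpec()))
})
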