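test_that("wavelength update follows the canonical schedule", {
  # worst wave: exponent -> -1, wavelength divided by alpha
  expect_equal(updateWavelength(0.5, f = 10, fmax = 10, fmin = 2,
                                alpha = 1.0026),
               0.5 / 1.0026, tolerance = 1e-9)
  # best wave: exponent -> 0 when eps << fitness range
  expect_equal(updateWavelength(0.5, f = 2, fmax = 10, fmin = 2,
                                alpha = 1.0026), 0.5, tolerance = 1e-6)
  # midway fitness with alpha = 2: delta * 2^(-1/2)
  expect_equal(updateWavelength(1, f = 5, fmax = 8, fmin = 2, alpha = 2,
                                epsilon = 1e-15), 2^(-0.5),
               tolerance = 1e-9)
  expect_gt(updateWavelength(1e-6, 1, 1, 0), 0)
})

test_that("propagation: zero wavelength fixes the wave, steps stay bounded", {
  set.seed(1)
  x <- runif(10, -3, 3)
  expect_equal(wavePropagate(x, 0, rep(-5, 10), rep(5, 10)), x)
  for (i in 1:50) {
    xn <- wavePropagate(x, 0.1, rep(-5, 10), rep(5, 10))
    expect_true(all(xn >= -5 & xn <= 5))
    expect_true(all(abs(xn - x) <= 0.1 * 10 + 1e-12 | (xn >= -5 & xn <= 5)))
  }
})

test_that("propagation step size has mean |dx| = delta*L/2 (Monte-Carlo)", {
  # one 1e5-dimensional call = 1e5 independent 1-D draws; in-bounds regime
  set.seed(42)
  D <- 1e5
  x <- numeric(D)
  xn <- wavePropagate(x, 0.1, rep(-10, D), rep(10, D))
  expect_equal(mean(abs(xn - x)), 0.1 * 20 / 2, tolerance = 0.02)
})

test_that("refraction centres on the midpoint and rescales the wavelength", {
  # degenerate case: wave already at the best position
  set.seed(2)
  r <- waveRefract(c(1, 2), c(1, 2), 0.5, fOld = 3, fNew = 1)
  expect_equal(r$position, c(1, 2))
  expect_equal(r$wavelength, 0.5 * 3)
  # adopted wavelength revision: f(old)=2, f(new)=1 doubles delta
  r2 <- waveRefract(0, 0, 1, fOld = 2, fNew = 1)
  expect_equal(r2$wavelength, 2)
  # Monte-Carlo: sample mean of the refracted coordinate
  set.seed(3)
  D <- 1e5
  r3 <- waveRefract(rep(1, D), rep(5, D), 1, fOld = 1)
  se <- (abs(5 - 1) / 2) / sqrt(D)
  expect_lt(abs(mean(r3$position) - 3), 3 * se)
})

test_that("whale coefficients have the prescribed ranges and coverage", {
  set.seed(4)
  co <- woaCoefficients(0, 100)
  expect_true(all(co$A == 0))
  co2 <- woaCoefficients(2, 1e4)
  expect_true(all(co2$A >= -2 & co2$A <= 2))
  expect_true(all(co2$C >= 0 & co2$C <= 2))
  # empirical coverage of the full ranges
  expect_lt(min(co2$A), -1.9); expect_gt(max(co2$A), 1.9)
  expect_lt(min(co2$C), 0.05); expect_gt(max(co2$C), 1.95)
  expect_error(woaCoefficients(3), "a <= 2")
})

test_that("whale move primitives reproduce the hand-computed updates", {
  # encircle: X*=5, X=3, A=0.5, C=1 -> D=2, X'=4
  expect_equal(woaEncircle(3, 5, A = 0.5, C = 1), 4)
  # A = 0 collapses onto the best position
  expect_equal(woaEncircle(c(1, 7), c(2, 2), A = c(0, 0), C = c(1.3, 0.2)),
               c(2, 2))
  # explore: Xrand=10, X=2, C=1, A=2 -> D=8, X'=-6
  expect_equal(woaExplore(2, 10, A = 2, C = 1), -6)
  # spiral at l=0: X' = |X*-X| + X*
  expect_equal(woaSpiral(3, 5, b = 1, l = 0), 7)
})

test_that("optimizer is elitist and keeps every agent in bounds", {
  for (seed in 1:5) {
    seen <- new.env(); seen$bad <- FALSE
    obj <- function(x) {
      if (any(x < -5 - 1e-9 | x > 5 + 1e-9)) seen$bad <- TRUE
      sum(x^2)
    }
    r <- hybOptimize(obj, rep(-5, 5), rep(5, 5),
                     hybWaveConfig(10, 40, seed = seed))
    expect_true(all(diff(fitnessTrace(r)) <= 0))
    expect_false(seen$bad)
    expect_true(all(r@bestPosition >= -5 & r@bestPosition <= 5))
  }
})

test_that("an initially optimal solution is never lost", {
  # objective minimized at a point every run stumbles on immediately
  obj <- function(x) sum((x - 0.5)^2)
  r <- hybOptimize(obj, rep(0, 2), rep(1, 2), hybWaveConfig(30, 30, seed = 9))
  f0 <- fitnessTrace(r)[1]
  expect_true(all(fitnessTrace(r) <= f0))
  expect_equal(r@bestFitness, min(fitnessTrace(r)))
})

test_that("pHybrid=1 reduces to an independently coded water-wave optimizer", {
  seeds <- 1:8
  lb <- rep(-5, 10); ub <- rep(5, 10)
  hyb <- vapply(seeds, function(s)
    hybOptimize(sphereFunction, lb, ub,
                hybWaveConfig(20, 100, pHybrid = 1, seed = s))@bestFitness,
    numeric(1))
  ref <- vapply(seeds, function(s)
    refWWO(sphereFunction, lb, ub, 20, 100, s), numeric(1))
  # same algorithm class: median final fitness within 2 orders of magnitude
  # (pure WOA sits ~11 orders away, see below)
  expect_lt(abs(median(log10(hyb)) - median(log10(ref))), 2)
})

test_that("pHybrid=0 without refraction reduces to a whale optimizer", {
  seeds <- 1:8
  lb <- rep(-5, 10); ub <- rep(5, 10)
  hyb <- vapply(seeds, function(s)
    hybOptimize(sphereFunction, lb, ub,
                hybWaveConfig(20, 100, pHybrid = 0, hMax = 200L,
                              seed = s))@bestFitness, numeric(1))
  ref <- vapply(seeds, function(s)
    refWOA(sphereFunction, lb, ub, 20, 100, s), numeric(1))
  expect_lt(abs(median(log10(hyb)) - median(log10(ref))), 2)
  # and the two reductions are genuinely different algorithms
  wwo <- vapply(seeds, function(s)
    refWWO(sphereFunction, lb, ub, 20, 100, s), numeric(1))
  expect_gt(abs(median(log10(wwo)) - median(log10(ref))), 4)
})

test_that("runs are exactly reproducible from the seed", {
  cfg <- hybWaveConfig(10, 30, seed = 11)
  r1 <- hybOptimize(rastriginFunction, rep(-5.12, 5), rep(5.12, 5), cfg)
  r2 <- hybOptimize(rastriginFunction, rep(-5.12, 5), rep(5.12, 5), cfg)
  expect_identical(r1@bestPosition, r2@bestPosition)
  expect_identical(fitnessTrace(r1), fitnessTrace(r2))
})
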