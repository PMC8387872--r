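test_that("constructors enforce type invariants", {
  expect_error(ogden_model(mu = -1, alpha = 2), "mu")
  expect_error(ogden_model(mu = 100, alpha = 0), "alpha")
  expect_error(ogden_model(mu = 100, alpha = 2, poisson_ratio = 0.5), "poisson")
  expect_error(prony_series(g_i = c(0.6, 0.6), beta = c(1, 10)), "exceed 1")
  expect_error(prony_series(g_i = c(0.2, 0.2), beta = c(10, 1)), "increasing")
  expect_error(prony_series(g_i = c(0.2, 1.2), beta = c(1, 10)), "\\(0, 1\\]")
  expect_error(strain_history(c(0, 1), c(0.9, 1)), "stretch 1")
  expect_error(strain_history(c(0.5, 1), c(1, 0.9)), "start at time 0")
})

test_that("strain energy vanishes at reference and is isotropic", {
  m <- cord_truth()$elastic
  expect_equal(ogden_strain_energy(m, c(1, 1, 1), 1), 0)
  s <- c(0.8, 1.1, 1.25)
  perms <- list(s, s[c(2, 1, 3)], s[c(3, 2, 1)], s[c(2, 3, 1)])
  vals <- vapply(perms, function(p) ogden_strain_energy(m, p, 1), 0.0)
  expect_equal(vals, rep(vals[1], 4))
  expect_error(ogden_strain_energy(m, c(-1, 1, 1), 1), "> 0")
  expect_error(ogden_strain_energy(m, c(1, 1, 1), 0), "> 0")
})

test_that("strain energy matches term-by-term evaluation at cord parameters", {
  m <- cord_truth()$elastic
  lam <- c(0.8, 1.1180, 1.1180)
  # independent arithmetic: one-term Ogden with J = 1 plus zero volumetric
  expected <- cord_mu / cord_alpha * (sum(lam^cord_alpha) - 3)
  expect_equal(ogden_strain_energy(m, lam, relative_volume = 1), expected,
               tolerance = 1e-12)
})

test_that("uniaxial nominal stress matches dW/dlambda and tangent stiffness", {
  m <- cord_truth()$elastic
  expect_equal(uniaxial_nominal_stress(m, 1), 0)
  # tangent stiffness at the reference: 3 * sum(mu * alpha) / 2
  h <- 1e-6
  tangent <- (uniaxial_nominal_stress(m, 1 + h) -
              uniaxial_nominal_stress(m, 1 - h)) / (2 * h)
  expect_equal(tangent, 3 * cord_mu * cord_alpha / 2, tolerance = 1e-6)
  expect_equal(tangent, 2357.5, tolerance = 1e-4)
  # finite-difference of the incompressible energy restriction, several stretches
  for (lam in c(0.6, 0.85, 1.2, 1.6)) {
    w <- function(l) ogden_strain_energy(m, c(l, 1 / sqrt(l), 1 / sqrt(l)), 1)
    expect_equal(uniaxial_nominal_stress(m, lam),
                 (w(lam + h) - w(lam - h)) / (2 * h), tolerance = 1e-6)
  }
  # sign convention: compressive stretch gives negative nominal stress
  expect_lt(uniaxial_nominal_stress(m, 0.8), 0)
  expect_error(uniaxial_nominal_stress(m, -0.1), "> 0")
})

test_that("reduced relaxation is normalized, monotone, and convex", {
  p <- cord_truth()$relaxation
  expect_equal(reduced_relaxation(p, 0), 1, tolerance = 1e-12)
  expect_equal(reduced_relaxation(p, 1e9), 1 - sum(cord_g), tolerance = 1e-12)
  expect_equal(1 - sum(cord_g), 0.265)
  tt <- seq(0, 2, length.out = 400)
  g <- reduced_relaxation(p, tt)
  expect_true(all(diff(g) < 0))
  expect_true(all(diff(diff(g)) > 0))
  expect_error(reduced_relaxation(p, -1), ">= 0")
})

test_that("small-strain moduli follow the closed forms", {
  m <- cord_truth()$elastic
  mod <- small_strain_moduli(m)
  expect_equal(mod[["shear"]], 785.84, tolerance = 1e-6)
  expect_equal(mod[["young"]], 2 * 785.84 * 1.499, tolerance = 1e-6)
  p <- pia_truth()
  expect_equal(small_strain_moduli(p)[["shear"]], 264.18e3, tolerance = 1e-4)
  # nu -> 0 limit: K = 2 G0 / 3
  m0 <- ogden_model(100, 2, poisson_ratio = 1e-12)
  mods <- small_strain_moduli(m0)
  expect_equal(mods[["bulk"]], 2 * mods[["shear"]] / 3, tolerance = 1e-9)
})

test_that("qlv stress of an undeformed history is identically zero", {
  tr <- qlv_stress(cord_truth(), strain_history(c(0, 0.5, 1), c(1, 1, 1)))
  expect_true(all(tr$stresses == 0))
  expect_identical(tr$stresses[1], 0)
})

test_that("qlv ramp-and-hold relaxes to the equilibrium fraction", {
  mat <- cord_truth()
  # ramp to lambda = 0.7 over 0.02 s, hold for many slow time constants
  t_ramp <- 0.02; t_hold <- 6
  tt <- c(seq(0, t_ramp, length.out = 60), seq(t_ramp * 1.01, t_hold, length.out = 300))
  lam <- c(seq(1, 0.7, length.out = 60), rep(0.7, 300))
  tr <- qlv_stress(mat, strain_history(tt, lam))
  terminal <- tr$stresses[length(tr$stresses)]
  sig_e <- uniaxial_nominal_stress(mat$elastic, 0.7)
  expect_equal(terminal / sig_e, 1 - sum(cord_g), tolerance = 0.01)
})

test_that("qlv instantaneous and equilibrium rate limits hold within 1%", {
  mat <- cord_truth()
  sig_e <- uniaxial_nominal_stress(mat$elastic, 0.7)
  fast <- ramp_protocol(100 * max(cord_beta), 0.3, "compression", 80)
  slow <- ramp_protocol(min(cord_beta) / 100 / 10, 0.3, "compression", 80)
  cv_fast <- simulate_ramp_test(mat, fast)
  cv_slow <- simulate_ramp_test(mat, slow)
  expect_equal(cv_fast$stress[80] / abs(sig_e), 1, tolerance = 0.01)
  expect_equal(cv_slow$stress[80] / abs(sig_e), 1 - sum(cord_g), tolerance = 0.01)
})

test_that("recurrence matches trapezoidal quadrature on random histories", {
  mat <- cord_truth()
  for (s in 1:100) {
    set.seed(s)
    n <- 200
    span <- runif(1, 0.02, 0.1)
    tt <- seq(0, span, length.out = n)
    # random monotone-ish piecewise-linear compression history
    steps <- abs(rnorm(n - 1))
    lam <- 1 - runif(1, 0.1, 0.35) * cumsum(c(0, steps)) / sum(steps)
    lam[1] <- 1
    tr <- qlv_stress(mat, strain_history(tt, lam))
    at <- round(seq(50, length(tr$times), length.out = 12))
    lam_grid <- stats::approx(tt, lam, xout = tr$times)$y
    oracle <- qlv_trapezoid_oracle(mat, tr$times, lam_grid, at)
    rel <- abs(tr$stresses[at] - oracle) / pmax(abs(oracle), 1e-9)
    expect_lt(max(rel), 0.001)
  }
})

test_that("stress magnitude at fixed strain is non-decreasing in strain rate", {
  mat <- cord_truth()
  stresses <- vapply(c(0.32, 2.83, 25.44, 77.22), function(r) {
    cv <- simulate_ramp_test(mat, ramp_protocol(r, 0.4, "compression", 100))
    stats::approx(cv$strain, cv$stress, xout = 0.3)$y
  }, 0.0)
  expect_true(all(diff(stresses) > 0))
})

test_that("overstress formulation tends to the hyperelastic curve when slow", {
  mat <- cord_truth()
  slow <- ramp_protocol(0.002, 0.3, "compression", 60)
  cv <- simulate_ramp_test(mat, slow, formulation = "overstress")
  hyper <- abs(uniaxial_nominal_stress(mat$elastic, 0.7))
  expect_equal(cv$stress[60] / hyper, 1, tolerance = 0.02)
})

test_that("exponent overflow raises a domain error instead of clamping", {
  m <- ogden_model(100, 30)
  expect_error(uniaxial_nominal_stress(m, 1e12), "overflow")
})
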