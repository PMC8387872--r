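test_that("curve discrepancy is zero iff curves coincide, one at 2x", {
  cv <- simulate_pia_tension(pia_truth(), ramp_protocol(0.05, 0.3, "tension", 60))
  expect_equal(curve_discrepancy(cv, cv), 0)
  dbl <- stress_strain_curve(cv$strain, 2 * cv$stress, cv$rate, cv$mode)
  expect_equal(curve_discrepancy(dbl, cv), 1, tolerance = 1e-9)
  expect_gt(curve_discrepancy(dbl, cv), 0)
  far <- stress_strain_curve(cv$strain + 5, cv$stress, cv$rate, cv$mode)
  expect_error(curve_discrepancy(far, cv), "overlap")
})

test_that("curve discrepancy matches hand-integrated trapezoid areas", {
  target <- stress_strain_curve(c(0, 0.1, 0.2), c(0, 100, 300), 1, "tension")
  model <- stress_strain_curve(c(0, 0.1, 0.2), c(0, 150, 350), 1, "tension")
  # hand arithmetic on the piecewise-linear interpolants:
  #   integral of (model - target) = 2.5 + 5     = 7.5
  #   integral of |target|         = 5 + 20      = 25          -> area 0.3
  #   mean (model-target)^2        = 50^2 * 2/3  (continuum limit)
  #   mean target^2                = (100^2/3 + 130000/3) / 2
  area <- 7.5 / 25
  l2 <- (50 * sqrt(2 / 3)) / sqrt((100^2 / 3 + 130000 / 3) / 2)
  expect_equal(curve_discrepancy(model, target), 0.5 * area + 0.5 * l2,
               tolerance = 0.01)
})

test_that("pia fit exactly recovers noise-free generating parameters", {
  curve <- generate_pia_curve(pia_truth())
  res <- fit_pia_ogden(curve)
  expect_true(res$converged)
  expect_equal(res$material$mu, pia_mu, tolerance = 0.01)
  expect_equal(res$material$alpha, pia_alpha, tolerance = 0.01)
  expect_equal(res$per_rate$r2, 1, tolerance = 1e-6)
})

test_that("pia fit scales: stress * c recovers mu * c with alpha unchanged", {
  curve <- generate_pia_curve(pia_truth())
  base <- fit_pia_ogden(curve)
  for (c_fac in c(0.1, 3)) {
    scaled <- stress_strain_curve(curve$strain, c_fac * curve$stress,
                                  curve$rate, curve$mode)
    res <- fit_pia_ogden(scaled)
    expect_equal(res$material$mu, c_fac * base$material$mu, tolerance = 1e-6)
    expect_equal(res$material$alpha, base$material$alpha, tolerance = 1e-6)
  }
})

test_that("degenerate constant curve yields a non-converged pia result", {
  flat <- stress_strain_curve(seq(0, 0.3, length.out = 10), rep(5, 10),
                              0.05, "tension")
  res <- fit_pia_ogden(flat)
  expect_false(res$converged)
  expect_null(res$material)
  expect_error(fit_pia_ogden(stress_strain_curve(c(0, 0.1), c(0, 1), 1, "tension")),
               "5 samples")
})

noise_free_curves <- generate_cord_curves(cord_truth(),
                                          noise = curve_noise_model(0, 1, 1))

test_that("multi-rate cord fit recovers Table-level truth from a perturbed start", {
  res <- fit_cord_qlv(noise_free_curves, perturbed_cord_config(11))
  m <- res$material
  expect_true(res$converged)
  expect_equal(m$elastic$mu, cord_mu, tolerance = 0.05)
  expect_equal(m$elastic$alpha, cord_alpha, tolerance = 0.05)
  expect_equal(m$relaxation$g_i, cord_g, tolerance = 0.10)
  expect_lte(sum(m$relaxation$g_i), 1)
  expect_true(all(res$per_rate$r2 > 0.99))
})

test_that("cord fit is idempotent: refitting its own curves reproduces it", {
  res <- fit_cord_qlv(noise_free_curves, perturbed_cord_config(3))
  regen <- generate_cord_curves(res$material, noise = curve_noise_model(0, 1, 1))
  cfg2 <- fit_config(mu_init = res$material$elastic$mu,
                     alpha_init = res$material$elastic$alpha,
                     g_init = res$material$relaxation$g_i,
                     beta_init = cord_beta, seed = 3)
  res2 <- fit_cord_qlv(regen, cfg2)
  expect_equal(res2$material$elastic$mu, res$material$elastic$mu, tolerance = 0.005)
  expect_equal(res2$material$elastic$alpha, res$material$elastic$alpha,
               tolerance = 0.005)
  expect_equal(res2$material$relaxation$g_i, res$material$relaxation$g_i,
               tolerance = 0.02)
})

test_that("infeasible initial sum(G) = 1.2 returns a feasible constrained fit", {
  cfg <- fit_config(mu_init = 150, alpha_init = 6,
                    g_init = c(0.4, 0.4, 0.4),   # sums to 1.2
                    beta_init = cord_beta, seed = 2, mode = "staged")
  res <- fit_cord_qlv(noise_free_curves, cfg)
  expect_lte(sum(res$material$relaxation$g_i), 1)
  expect_true(all(res$material$relaxation$g_i > 0))
})

test_that("staged-only and hyperelastic-stage variants return valid materials", {
  cfg <- perturbed_cord_config(4, mode = "staged", stage1 = "hyperelastic")
  res <- fit_cord_qlv(noise_free_curves, cfg)
  m <- res$material
  expect_s3_class(m, "qlv_material")
  expect_lte(sum(m$relaxation$g_i), 1)
  # the hyperelastic stage-1 reading absorbs the relaxation already present
  # at 0.32 1/s into mu, biasing it low by roughly the relaxed fraction --
  # this variant documents that ambiguity rather than resolving it
  expect_lt(m$elastic$mu, cord_mu)
  expect_gt(m$elastic$mu, 0.1 * cord_mu)
})

# Parameter-recovery property, scaled down from the 20-seed study run during
# development (20/20 recovered; see scripts/acceptance.R for the seeded run):
# 6 perturbation seeds here to stay inside the suite's time budget.
test_that("recovery from +/-30% perturbed starts succeeds for >= 5 of 6 seeds", {
  ok <- 0L
  for (s in 1:6) {
    res <- fit_cord_qlv(noise_free_curves, perturbed_cord_config(s))
    m <- res$material
    errs <- abs(c(m$elastic$mu / cord_mu, m$elastic$alpha / cord_alpha,
                  m$relaxation$g_i / cord_g) - 1)
    if (all(errs < 0.10)) ok <- ok + 1L
    expect_lte(sum(m$relaxation$g_i), 1)        # no constraint leakage, ever
  }
  expect_gte(ok, 5L)
})

test_that("2% multiplicative noise keeps median mu bias below 10%", {
  mus <- vapply(1:3, function(s) {
    noisy <- generate_cord_curves(cord_truth(),
                                  noise = curve_noise_model(0.02, 1, 100 + s))
    res <- fit_cord_qlv(noisy, perturbed_cord_config(s, max_iter = 300L))
    res$material$elastic$mu
  }, 0.0)
  expect_lt(abs(stats::median(mus) / cord_mu - 1), 0.10)
})
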