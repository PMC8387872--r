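#' Multiplicative curve noise model
#'
#' Log-normal multiplicative noise applied per stress sample, emulating
#' specimen-to-specimen scatter that scales with stress level. The
#' log-normal draw is mean-corrected so the expected noisy stress equals
#' the noise-free stress.
#'
#' @param relative_sd relative standard deviation (>= 0; 0 disables noise).
#' @param specimen_count number of replicate specimens per condition.
#' @param seed integer seed; every generator is a deterministic function
#'   of (parameters, seed).
#' @return An object of class `curve_noise_model`.
#' @export
curve_noise_model <- function(relative_sd = 0, specimen_count = 1L, seed = 1L) {
  if (relative_sd < 0) stop("`relative_sd` must be >= 0")
  if (specimen_count < 1L) stop("`specimen_count` must be >= 1")
  structure(list(relative_sd = relative_sd,
                 specimen_count = as.integer(specimen_count),
                 seed = as.integer(seed)),
            class = "curve_noise_model")
}

# run `expr` under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.apply_curve_noise <- function(stress, relative_sd) {
  if (relative_sd == 0) return(stress)
  sdlog <- sqrt(log(1 + relative_sd^2))
  # E[exp(N(-sdlog^2/2, sdlog^2))] = 1: noisy mean matches the clean curve
  stress * exp(stats::rnorm(length(stress), -sdlog^2 / 2, sdlog))
}

#' Generate synthetic unconfined-compression cord curves
#'
#' Emulates the multi-rate unconfined compression experiments on spinal
#' cord white matter: one ramp simulation per strain rate per specimen,
#' with multiplicative log-normal noise per sample. Default rates are the
#' four experimental rates 0.32, 2.83, 25.44 and 77.22 1/s.
#'
#' @param material the generating [qlv_material()].
#' @param rates nominal engineering strain rates in 1/s.
#' @param max_strain ramp target strain (default 0.4).
#' @param noise a [curve_noise_model()].
#' @param sample_count samples per curve.
#' @return A list of [stress_strain_curve()], ordered specimen-major
#'   (all rates for specimen 1, then specimen 2, ...). Each curve carries
#'   a `specimen` attribute.
#' @export
generate_cord_curves <- function(material,
                                 rates = c(0.32, 2.83, 25.44, 77.22),
                                 max_strain = 0.4,
                                 noise = curve_noise_model(),
                                 sample_count = 120L) {
  stopifnot(inherits(material, "qlv_material"), inherits(noise, "curve_noise_model"))
  if (any(rates <= 0)) stop("all rates must be > 0")
  clean <- lapply(rates, function(r)
    simulate_ramp_test(material, ramp_protocol(r, max_strain, "compression",
                                               sample_count)))
  .with_seed(noise$seed, {
    out <- list()
    for (sp in seq_len(noise$specimen_count)) {
      for (j in seq_along(rates)) {
        cv <- clean[[j]]
        noisy <- stress_strain_curve(cv$strain,
                                     .apply_curve_noise(cv$stress, noise$relative_sd),
                                     cv$rate, cv$mode)
        attr(noisy, "specimen") <- sp
        out[[length(out) + 1L]] <- noisy
      }
    }
    out
  })
}

#' Generate a synthetic pia mater tension curve
#'
#' Emulates the quasi-static (default 0.05 1/s) tensile test on pia mater
#' from a hyperelastic Ogden model, with optional multiplicative noise.
#'
#' @param model the generating [ogden_model()].
#' @param rate nominal strain rate label in 1/s.
#' @param max_strain ramp target strain.
#' @param noise a [curve_noise_model()] (first specimen only is returned
#'   when `specimen_count == 1`, otherwise a list).
#' @param sample_count samples per curve.
#' @return A [stress_strain_curve()] (or list of them for multiple
#'   specimens).
#' @export
generate_pia_curve <- function(model, rate = 0.05, max_strain = 0.4,
                               noise = curve_noise_model(),
                               sample_count = 120L) {
  stopifnot(inherits(model, "ogden_model"), inherits(noise, "curve_noise_model"))
  clean <- simulate_pia_tension(model, ramp_protocol(rate, max_strain,
                                                     "tension", sample_count))
  out <- .with_seed(noise$seed, {
    lapply(seq_len(noise$specimen_count), function(sp) {
      cv <- stress_strain_curve(clean$strain,
                                .apply_curve_noise(clean$stress, noise$relative_sd),
                                clean$rate, clean$mode)
      attr(cv, "specimen") <- sp
      cv
    })
  })
  if (noise$specimen_count == 1L) out[[1L]] else out
}

#' Generate a set of synthetic pellet impact trajectories
#'
#' Runs the impact surrogate, applies per-replicate velocity jitter
#' (emulating pellet-to-pellet velocity spread) and additive Gaussian
#' displacement noise, and resamples each record at the experimental
#' reporting rate (4,500 Hz by default).
#'
#' @param config an [impact_config()].
#' @param n number of replicates (>= 1).
#' @param noise_sd additive displacement noise SD in mm.
#' @param seed integer seed.
#' @param velocity_jitter relative SD of the per-replicate impact velocity.
#' @param sample_rate output sampling rate in Hz.
#' @param dt surrogate integration step in s.
#' @return A list of [trajectory()] objects; each carries a
#'   `velocity` attribute (the jittered impact velocity actually used).
#' @export
generate_trajectory_set <- function(config, n = 3L, noise_sd = 0, seed = 1L,
                                    velocity_jitter = 0, sample_rate = 4500,
                                    dt = 1e-6) {
  stopifnot(inherits(config, "impact_config"))
  if (n < 1L) stop("`n` must be >= 1")
  if (noise_sd < 0 || velocity_jitter < 0) stop("noise parameters must be >= 0")
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cfg <- config
      v <- config$impact_velocity *
        (if (velocity_jitter > 0) exp(stats::rnorm(1, 0, velocity_jitter)) else 1)
      cfg$impact_velocity <- v
      raw <- simulate_pellet_impact(cfg, dt = dt)
      grid <- seq(0, max(raw$times), by = 1 / sample_rate)
      u <- stats::approx(raw$times, raw$displacements, xout = grid)$y
      if (noise_sd > 0) {
        u <- u + stats::rnorm(length(u), 0, noise_sd)
        u[1] <- 0
      }
      tr <- trajectory(grid, u)
      attr(tr, "velocity") <- v
      tr
    })
  })
}

#' Generate a mesh-refinement convergence series
#'
#' Power-law convergence toward a known limit:
#' `f(h) = limit + coefficient * h^order`, with optional relative Gaussian
#' noise — the synthetic counterpart of a mesh-refinement study whose
#' Richardson extrapolation should recover `limit` and `order`.
#'
#' @param limit_value the zero-mesh-size solution.
#' @param order convergence order (> 0).
#' @param coefficient leading error coefficient.
#' @param mesh_sizes mesh sizes, coarsest first (default `c(0.8, 0.4, 0.2)`
#'   mm, a halving sequence).
#' @param noise_rel relative noise SD applied to each value.
#' @param seed integer seed (used only when `noise_rel > 0`).
#' @return A list with `mesh_sizes` and `values`.
#' @export
generate_convergence_series <- function(limit_value, order, coefficient,
                                        mesh_sizes = c(0.8, 0.4, 0.2),
                                        noise_rel = 0, seed = 1L) {
  if (order <= 0) stop("`order` must be > 0")
  vals <- limit_value + coefficient * mesh_sizes^order
  if (noise_rel > 0)
    vals <- .with_seed(seed, vals * (1 + stats::rnorm(length(vals), 0, noise_rel)))
  list(mesh_sizes = mesh_sizes, values = vals)
}
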