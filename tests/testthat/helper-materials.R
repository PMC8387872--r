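# Shared fixtures: reference materials and independent oracles.

cord_truth <- function() reference_cord_material()
pia_truth <- function() reference_pia_model()

cord_mu <- 209
cord_alpha <- 7.52
cord_g <- c(0.033, 0.296, 0.406)
cord_beta <- c(2, 13, 406)
pia_mu <- 42e3
pia_alpha <- 12.58

# Independent hereditary-integral oracle: trapezoidal (endpoint-averaged)
# quadrature of sigma(t) = int g(t - tau) dsigmaE, evaluated on the same
# time grid as a stress trace. Different discretization family from the
# package's midpoint exponential recurrence.
qlv_trapezoid_oracle <- function(material, times, stretches, at_idx) {
  sig_e <- uniaxial_nominal_stress(material$elastic, stretches)
  d_sig <- diff(sig_e)
  g <- function(t) reduced_relaxation(material$relaxation, t)
  vapply(at_idx, function(k) {
    if (k < 2L) return(0)
    tk <- times[k]
    gl <- g(tk - times[1:(k - 1)])
    gr <- g(tk - times[2:k])
    sum((gl + gr) / 2 * d_sig[1:(k - 1)])
  }, 0.0)
}

# Perturbed fit configuration used by the recovery studies: +/-30%
# multiplicative perturbation of (mu, alpha, G_i), beta held at truth.
perturbed_cord_config <- function(seed, ...) {
  set.seed(seed)
  pert <- runif(5, 0.7, 1.3)
  fit_config(mu_init = cord_mu * pert[1],
             alpha_init = cord_alpha * pert[2],
             g_init = pmin(cord_g * pert[3:5], 0.95),
             beta_init = cord_beta, seed = seed, ...)
}

# Symmetric triangular displacement pulse; the descending limb continues
# at constant slope below zero so each phase is exactly polynomial.
triangle_trajectory <- function(peak_mm = 5, n_up = 40L, n_down = 50L,
                                dt = 1e-4) {
  up <- seq(0, peak_mm, length.out = n_up + 1L)
  slope <- peak_mm / n_up
  down <- peak_mm - slope * seq_len(n_down)
  u <- c(up, down)
  trajectory(seq_along(u) * dt - dt, u)
}
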