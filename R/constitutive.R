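#' Ogden hyperelastic model
#'
#' Constructs an isotropic Ogden hyperelastic material description in terms
#' of shear-like coefficients `mu` (Pa) and dimensionless exponents `alpha`.
#' The small-strain shear modulus of the model is
#' \eqn{G_0 = \sum_i \mu_i \alpha_i / 2}, which must be positive.
#'
#' The near-incompressible formulation carries a Poisson ratio
#' `poisson_ratio` strictly below 0.5; the bulk modulus is derived from
#' \eqn{K = 2 G_0 (1+\nu) / (3 (1 - 2\nu))}.
#'
#' @param mu numeric vector of coefficients in Pa, all positive.
#' @param alpha numeric vector of exponents, same length as `mu`, all nonzero.
#' @param poisson_ratio Poisson ratio in `(0, 0.5)` (strict).
#' @return An object of class `ogden_model`.
#' @examples
#' cord <- ogden_model(mu = 209, alpha = 7.52, poisson_ratio = 0.499)
#' small_strain_moduli(cord)
#' @export
ogden_model <- function(mu, alpha, poisson_ratio = 0.499) {
  if (length(mu) < 1L || length(mu) != length(alpha))
    stop("`mu` and `alpha` must be non-empty vectors of equal length")
  if (!all(is.finite(mu)) || !all(is.finite(alpha)) || !is.finite(poisson_ratio))
    stop("non-finite Ogden parameters")
  if (any(mu <= 0)) stop("all `mu` must be > 0")
  if (any(alpha == 0)) stop("all `alpha` must be nonzero")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("`poisson_ratio` must lie strictly in (0, 0.5)")
  g0 <- sum(mu * alpha) / 2
  if (g0 <= 0) stop("small-strain shear modulus sum(mu*alpha)/2 must be > 0")
  structure(
    list(mu = as.numeric(mu), alpha = as.numeric(alpha),
         poisson_ratio = as.numeric(poisson_ratio)),
    class = "ogden_model")
}

#' @export
print.ogden_model <- function(x, ...) {
  cat("Ogden hyperelastic model (", length(x$mu), " term",
      if (length(x$mu) > 1) "s", ")\n", sep = "")
  for (i in seq_along(x$mu))
    cat(sprintf("  mu_%d = %.6g Pa, alpha_%d = %.6g\n", i, x$mu[i], i, x$alpha[i]))
  m <- small_strain_moduli(x)
  cat(sprintf("  nu = %.4g, G0 = %.6g Pa, K = %.6g Pa\n",
              x$poisson_ratio, m[["shear"]], m[["bulk"]]))
  invisible(x)
}

#' Normalized Prony relaxation series
#'
#' Describes the time-dependent reduced relaxation function
#' \eqn{g(t) = (1 - \sum_i G_i) + \sum_i G_i e^{-\beta_i t}} through
#' normalized moduli `g_i` (dimensionless fractions of the instantaneous
#' modulus) and decay rates `beta` in 1/s. The long-term fraction
#' \eqn{G_\infty = 1 - \sum G_i} must be non-negative.
#'
#' @param g_i numeric vector of normalized moduli, each in `(0, 1]`,
#'   with `sum(g_i) <= 1`.
#' @param beta numeric vector of decay rates in 1/s, positive and strictly
#'   increasing.
#' @return An object of class `prony_series`.
#' @examples
#' cord_relax <- prony_series(g_i = c(0.033, 0.296, 0.406), beta = c(2, 13, 406))
#' reduced_relaxation(cord_relax, c(0, 0.1, 1))
#' @export
prony_series <- function(g_i, beta) {
  if (length(g_i) < 1L || length(g_i) != length(beta))
    stop("`g_i` and `beta` must be non-empty vectors of equal length")
  if (!all(is.finite(g_i)) || !all(is.finite(beta)))
    stop("non-finite Prony parameters")
  if (any(g_i <= 0) || any(g_i > 1)) stop("all `g_i` must lie in (0, 1]")
  if (sum(g_i) > 1 + 1e-12) stop("sum(g_i) must not exceed 1")
  if (any(beta <= 0)) stop("all `beta` must be > 0")
  if (is.unsorted(beta, strictly = TRUE)) stop("`beta` must be strictly increasing")
  structure(list(g_i = as.numeric(g_i), beta = as.numeric(beta)),
            class = "prony_series")
}

#' @export
print.prony_series <- function(x, ...) {
  cat("Prony relaxation series:\n")
  for (i in seq_along(x$g_i))
    cat(sprintf("  G_%d = %.4g, beta_%d = %.4g 1/s\n", i, x$g_i[i], i, x$beta[i]))
  cat(sprintf("  long-term fraction Ginf = %.4g\n", 1 - sum(x$g_i)))
  invisible(x)
}

#' Quasi-linear viscoelastic material
#'
#' Couples an instantaneous Ogden elastic response with a normalized Prony
#' reduced-relaxation function, following the quasi-linear viscoelastic
#' (QLV) separation \eqn{G(t, \varepsilon) = g(t)\,\sigma^E(\varepsilon)}.
#'
#' @param elastic an [ogden_model()].
#' @param relaxation a [prony_series()].
#' @return An object of class `qlv_material`.
#' @examples
#' cord <- qlv_material(
#'   elastic    = ogden_model(209, 7.52, 0.499),
#'   relaxation = prony_series(c(0.033, 0.296, 0.406), c(2, 13, 406)))
#' @export
qlv_material <- function(elastic, relaxation) {
  stopifnot(inherits(elastic, "ogden_model"), inherits(relaxation, "prony_series"))
  structure(list(elastic = elastic, relaxation = relaxation),
            class = "qlv_material")
}

#' @export
print.qlv_material <- function(x, ...) {
  cat("Quasi-linear viscoelastic material\n")
  print(x$elastic); print(x$relaxation)
  invisible(x)
}

#' Strain history for viscoelastic stress evaluation
#'
#' A sampled uniaxial stretch history \eqn{\lambda(t)}: `times` start at 0
#' and increase strictly; `stretches` start at 1 (rest) and stay positive.
#' Stretch below 1 is compression.
#'
#' @param times numeric vector of times in seconds.
#' @param stretches numeric vector of principal stretches.
#' @return An object of class `strain_history`.
#' @export
strain_history <- function(times, stretches) {
  if (length(times) < 2L || length(times) != length(stretches))
    stop("`times` and `stretches` must have equal length >= 2")
  if (!all(is.finite(times)) || !all(is.finite(stretches)))
    stop("non-finite strain history")
  if (times[1] != 0) stop("history must start at time 0")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (abs(stretches[1] - 1) > 1e-12) stop("history must start at stretch 1 (rest)")
  if (any(stretches <= 0)) stop("all stretches must be > 0")
  structure(list(times = as.numeric(times), stretches = as.numeric(stretches)),
            class = "strain_history")
}

# guarded power: lambda^a with overflow control on |a * log(lambda)|
.pow_guard <- function(lambda, a) {
  ex <- a * log(lambda)
  if (any(abs(ex) > 700))
    stop("exponent overflow in Ogden power law (|alpha * log(stretch)| > 700)")
  exp(ex)
}

#' Ogden strain energy density
#'
#' Evaluates the compressible (modified) Ogden strain energy density
#' \deqn{W = \sum_i \frac{\mu_i}{\alpha_i}
#'   ({\lambda_1^*}^{\alpha_i} + {\lambda_2^*}^{\alpha_i} +
#'    {\lambda_3^*}^{\alpha_i} - 3) + \tfrac{1}{2} K (J - 1)^2}
#' where \eqn{\lambda_k^* = \lambda_k J^{-1/3}} are deviatoric principal
#' stretches, `J` the relative volume, and the bulk modulus `K` is derived
#' from the small-strain shear modulus and Poisson ratio.
#'
#' @param model an [ogden_model()].
#' @param stretches numeric vector of three principal stretches, all > 0.
#' @param relative_volume relative volume `J > 0`; defaults to
#'   `prod(stretches)` (the kinematically consistent value).
#' @return Energy density in Pa (J/m^3).
#' @export
ogden_strain_energy <- function(model, stretches, relative_volume = prod(stretches)) {
  stopifnot(inherits(model, "ogden_model"))
  if (length(stretches) != 3L) stop("`stretches` must have length 3")
  if (any(!is.finite(stretches)) || any(stretches <= 0))
    stop("all principal stretches must be finite and > 0")
  if (!is.finite(relative_volume) || relative_volume <= 0)
    stop("`relative_volume` must be finite and > 0")
  j13 <- relative_volume^(-1 / 3)
  lam_dev <- stretches * j13
  dev <- 0
  for (i in seq_along(model$mu)) {
    a <- model$alpha[i]
    dev <- dev + model$mu[i] / a * (sum(.pow_guard(lam_dev, a)) - 3)
  }
  k <- small_strain_moduli(model)[["bulk"]]
  dev + 0.5 * k * (relative_volume - 1)^2
}

#' Uniaxial nominal stress of an incompressible Ogden solid
#'
#' Closed-form first Piola-Kirchhoff (nominal) stress for homogeneous
#' uniaxial loading of an incompressible Ogden material,
#' \deqn{P(\lambda) = \sum_i \mu_i
#'   (\lambda^{\alpha_i - 1} - \lambda^{-\alpha_i/2 - 1}),}
#' obtained by differentiating the isochoric restriction
#' \eqn{W(\lambda, \lambda^{-1/2}, \lambda^{-1/2})} with respect to
#' \eqn{\lambda}. Negative for compression (\eqn{\lambda < 1}).
#'
#' @param model an [ogden_model()].
#' @param stretch numeric vector of stretches, all > 0.
#' @return Nominal stress in Pa, vectorized over `stretch`.
#' @export
uniaxial_nominal_stress <- function(model, stretch) {
  stopifnot(inherits(model, "ogden_model"))
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("`stretch` must be finite and > 0")
  out <- numeric(length(stretch))
  for (i in seq_along(model$mu)) {
    a <- model$alpha[i]
    out <- out + model$mu[i] *
      (.pow_guard(stretch, a - 1) - .pow_guard(stretch, -a / 2 - 1))
  }
  out
}

#' Reduced relaxation function
#'
#' Evaluates the normalized reduced relaxation function
#' \eqn{g(t) = (1 - \sum G_i) + \sum G_i e^{-\beta_i t}} so that
#' \eqn{g(0) = 1} and \eqn{g(\infty) = 1 - \sum G_i}.
#'
#' @param prony a [prony_series()].
#' @param t numeric vector of times in seconds, all >= 0.
#' @return Dimensionless relaxation values, vectorized over `t`.
#' @export
reduced_relaxation <- function(prony, t) {
  stopifnot(inherits(prony, "prony_series"))
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  ginf <- 1 - sum(prony$g_i)
  ginf + as.numeric(crossprod(prony$g_i, exp(-prony$beta %o% t)))
}

#' Small-strain moduli of an Ogden model
#'
#' Consistency mapping from the Ogden coefficients and Poisson ratio to
#' linearized moduli: shear \eqn{G_0 = \sum \mu_i \alpha_i / 2}, Young
#' \eqn{E = 2 G_0 (1 + \nu)}, bulk \eqn{K = 2 G_0 (1+\nu)/(3(1-2\nu))}.
#'
#' @param model an [ogden_model()].
#' @return Named numeric vector with elements `shear`, `young`, `bulk` (Pa).
#' @export
small_strain_moduli <- function(model) {
  stopifnot(inherits(model, "ogden_model"))
  nu <- model$poisson_ratio
  if (nu >= 0.5) stop("Poisson ratio must be < 0.5 for a finite bulk modulus")
  g0 <- sum(model$mu * model$alpha) / 2
  e <- 2 * g0 * (1 + nu)
  k <- e / (3 * (1 - 2 * nu))
  c(shear = g0, young = e, bulk = k)
}

# Resample a strain history onto a uniform grid fine enough for the
# exponential recurrence: max(beta) * dt <= 0.1 and at least `min_points`
# samples over the span. Linear interpolation of the stretch signal.
.resample_history <- function(history, prony, min_points = 2000L) {
  span <- history$times[length(history$times)]
  dt_beta <- 0.1 / max(prony$beta)
  n <- max(min_points, ceiling(span / dt_beta) + 1L, length(history$times))
  tt <- seq(0, span, length.out = n)
  ss <- stats::approx(history$times, history$stretches, xout = tt)$y
  list(times = tt, stretches = ss)
}

#' Quasi-linear viscoelastic stress response
#'
#' Evaluates the QLV hereditary integral
#' \deqn{\sigma(t) = \int_0^t g(t - \tau)\,
#'   \frac{d\sigma^E(\varepsilon(\tau))}{d\tau}\, d\tau}
#' for a uniaxial stretch history, with the instantaneous elastic stress
#' \eqn{\sigma^E} given by [uniaxial_nominal_stress()]. The convolution is
#' computed with a per-term exponential internal-variable recurrence
#' (midpoint kernel, second-order accurate); the history is resampled
#' internally onto a grid with `max(beta) * dt <= 0.1` and at least 2000
#' points.
#'
#' Two formulations are exposed. The default `"normalized"` uses
#' \eqn{g(0) = 1}: the instantaneous step response equals \eqn{\sigma^E}
#' and infinitely slow loading tends to \eqn{(1 - \sum G_i)\sigma^E}.
#' The alternative `"overstress"` adds the viscous convolution on top of
#' the full hyperelastic stress, so quasi-static loading tends to
#' \eqn{\sigma^E} and the instantaneous response is
#' \eqn{(1 + \sum G_i)\sigma^E}.
#'
#' @param material a [qlv_material()].
#' @param history a [strain_history()].
#' @param formulation `"normalized"` (default) or `"overstress"`.
#' @return A list of class `stress_trace` with `times` (s) and `stresses`
#'   (Pa, nominal; sign follows the loading direction) on the internal
#'   evaluation grid.
#' @export
qlv_stress <- function(material, history,
                       formulation = c("normalized", "overstress")) {
  stopifnot(inherits(material, "qlv_material"), inherits(history, "strain_history"))
  formulation <- match.arg(formulation)
  rs <- .resample_history(history, material$relaxation)
  sig_e <- uniaxial_nominal_stress(material$elastic, rs$stretches)
  d_sig <- diff(sig_e)
  dt <- rs$times[2] - rs$times[1]
  g_i <- material$relaxation$g_i
  beta <- material$relaxation$beta
  n <- length(rs$times)
  visc <- numeric(n)
  for (i in seq_along(g_i)) {
    decay <- exp(-beta[i] * dt)
    # h[k] = decay * h[k-1] + G_i * exp(-beta dt / 2) * d_sig[k]
    h <- stats::filter(g_i[i] * sqrt(decay) * d_sig, decay, method = "recursive")
    visc[-1] <- visc[-1] + as.numeric(h)
  }
  stresses <- switch(formulation,
    normalized = (1 - sum(g_i)) * sig_e + visc,
    overstress = sig_e + visc)
  structure(list(times = rs$times, stresses = stresses), class = "stress_trace")
}
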