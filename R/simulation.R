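#' Stress-strain curve container
#'
#' Paired engineering strain / nominal stress samples at a labelled nominal
#' strain rate. By convention both compression and tension curves are
#' stored with positive strain and positive stress magnitudes, so curves
#' from different modes plot and fit identically.
#'
#' @param strain numeric vector of engineering strains (>= 0, increasing).
#' @param stress numeric vector of nominal stresses in Pa.
#' @param rate nominal engineering strain rate in 1/s.
#' @param mode `"compression"` or `"tension"` (label only).
#' @return An object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress, rate,
                                mode = c("compression", "tension")) {
  mode <- match.arg(mode)
  if (length(strain) < 2L || length(strain) != length(stress))
    stop("`strain` and `stress` must have equal length >= 2")
  if (!all(is.finite(strain)) || !all(is.finite(stress)))
    stop("non-finite curve samples")
  if (is.unsorted(strain)) stop("`strain` must be non-decreasing")
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be > 0")
  structure(list(strain = as.numeric(strain), stress = as.numeric(stress),
                 rate = as.numeric(rate), mode = mode),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("stress-strain curve (%s): %d samples, rate %.4g 1/s, strain [%.3g, %.3g]\n",
              x$mode, length(x$strain), x$rate, min(x$strain), max(x$strain)))
  invisible(x)
}

#' Constant-rate ramp protocol
#'
#' Loading protocol for a homogeneous "single element" test: a constant
#' engineering strain rate ramp from zero strain to `max_strain`.
#'
#' @param rate engineering strain rate in 1/s, > 0.
#' @param max_strain target engineering strain in `(0, 1)`.
#' @param mode `"compression"` or `"tension"`.
#' @param sample_count number of output samples (>= 2).
#' @return An object of class `ramp_protocol`; `duration` is
#'   `max_strain / rate` seconds.
#' @export
ramp_protocol <- function(rate, max_strain, mode = c("compression", "tension"),
                          sample_count = 200L) {
  mode <- match.arg(mode)
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be > 0")
  if (!is.finite(max_strain) || max_strain <= 0 || max_strain >= 1)
    stop("`max_strain` must lie in (0, 1)")
  if (sample_count < 2L) stop("`sample_count` must be >= 2")
  structure(list(rate = rate, max_strain = max_strain, mode = mode,
                 sample_count = as.integer(sample_count),
                 duration = max_strain / rate),
            class = "ramp_protocol")
}

#' Simulate a constant-rate viscoelastic ramp test
#'
#' Builds the constant-engineering-rate stretch history implied by the
#' protocol, evaluates the QLV stress response, and returns the
#' engineering strain / nominal stress curve on `[0, max_strain]`.
#' Compression results are reported with positive compressive strain
#' (`1 - lambda`) and positive compressive stress.
#'
#' @param material a [qlv_material()].
#' @param protocol a [ramp_protocol()].
#' @param formulation passed to [qlv_stress()].
#' @return A [stress_strain_curve()].
#' @export
simulate_ramp_test <- function(material, protocol,
                               formulation = c("normalized", "overstress")) {
  stopifnot(inherits(material, "qlv_material"), inherits(protocol, "ramp_protocol"))
  formulation <- match.arg(formulation)
  sgn <- if (protocol$mode == "compression") -1 else 1
  n_hist <- max(protocol$sample_count, 64L)
  tt <- seq(0, protocol$duration, length.out = n_hist)
  hist <- strain_history(tt, 1 + sgn * protocol$rate * tt)
  trace <- qlv_stress(material, hist, formulation = formulation)
  strain_grid <- seq(0, protocol$max_strain, length.out = protocol$sample_count)
  trace_strain <- protocol$rate * trace$times
  stress <- stats::approx(trace_strain, sgn * trace$stresses, xout = strain_grid)$y
  stress_strain_curve(strain_grid, stress, protocol$rate, protocol$mode)
}

#' Simulate quasi-static tension of the pia mater
#'
#' Rate-independent hyperelastic tension curve from the closed-form
#' uniaxial Ogden stress. The protocol's rate is carried through as a
#' label only.
#'
#' @param model an [ogden_model()] for the pia mater.
#' @param protocol a [ramp_protocol()] with `mode = "tension"`.
#' @return A [stress_strain_curve()].
#' @export
simulate_pia_tension <- function(model, protocol) {
  stopifnot(inherits(model, "ogden_model"), inherits(protocol, "ramp_protocol"))
  if (protocol$mode != "tension") stop("pia tension protocol must have mode = 'tension'")
  strain <- seq(0, protocol$max_strain, length.out = protocol$sample_count)
  stress <- uniaxial_nominal_stress(model, 1 + strain)
  stress_strain_curve(strain, stress, protocol$rate, "tension")
}

#' Pellet impact configuration
#'
#' Set-up constants for the reduced-order transverse impact surrogate:
#' a rigid pellet of given mass and contact area strikes the spinal
#' cord-pia complex resting on a rigid support. Defaults follow the
#' ex-vivo bovine test configuration (7 g pellet, 4.5 m/s, pellet I
#' contact area 314 mm^2, 8 % axial prestrain, 0.13 mm pia).
#'
#' @param cord_material a [qlv_material()] for the parenchyma.
#' @param pia_material an [ogden_model()] for the pia mater.
#' @param pellet_mass pellet mass in kg.
#' @param pellet_area pellet contact area in mm^2.
#' @param impact_velocity initial pellet velocity in m/s.
#' @param cord_height anterior-posterior cord dimension in mm.
#' @param pia_thickness pia mater thickness in mm (>= 0; 0 removes the pia).
#' @param axial_prestrain axial engineering prestrain applied to the
#'   specimen before impact (enters as a pia/cord stretch offset).
#' @return An object of class `impact_config`.
#' @export
impact_config <- function(cord_material, pia_material,
                          pellet_mass = 0.007, pellet_area = 314,
                          impact_velocity = 4.5, cord_height = 10,
                          pia_thickness = 0.13, axial_prestrain = 0.08) {
  stopifnot(inherits(cord_material, "qlv_material"),
            inherits(pia_material, "ogden_model"))
  if (pellet_mass <= 0 || pellet_area <= 0 || cord_height <= 0)
    stop("mass, area and cord height must be > 0")
  if (impact_velocity < 0) stop("`impact_velocity` must be >= 0")
  if (pia_thickness < 0) stop("`pia_thickness` must be >= 0")
  if (axial_prestrain < 0 || axial_prestrain >= 1)
    stop("`axial_prestrain` must lie in [0, 1)")
  structure(list(cord_material = cord_material, pia_material = pia_material,
                 pellet_mass = pellet_mass, pellet_area = pellet_area,
                 impact_velocity = impact_velocity, cord_height = cord_height,
                 pia_thickness = pia_thickness, axial_prestrain = axial_prestrain),
            class = "impact_config")
}

#' Pellet displacement trajectory
#'
#' Time-stamped pellet displacement record, positive into the cord.
#'
#' @param times numeric vector of times in s, strictly increasing.
#' @param displacements numeric vector of displacements in mm; first is 0.
#' @param phases optional character vector of per-sample phase labels
#'   (`"loading"`, `"rebound"`, `"unloading"`).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, displacements, phases = NULL) {
  if (length(times) < 2L || length(times) != length(displacements))
    stop("`times` and `displacements` must have equal length >= 2")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (abs(displacements[1]) > 1e-9) stop("trajectory must start at displacement 0")
  if (!is.null(phases) && length(phases) != length(times))
    stop("`phases` must match sample count")
  structure(list(times = as.numeric(times),
                 displacements = as.numeric(displacements),
                 phases = phases),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("pellet trajectory: %d samples over %.3g ms, peak %.3g mm\n",
              length(x$times), 1000 * max(x$times), max(x$displacements)))
  invisible(x)
}

# pia membrane restoring force (N) for pellet deflection u (m).
# Two inclined tension strips anchored one cord diameter from the pellet
# edge; strip width = pellet diameter; tension from the uniaxial Ogden
# closed form on the stretched arc, clamped non-negative (no compression).
.pia_force <- function(config, u) {
  if (config$pia_thickness <= 0 || u <= 0) return(0)
  anchor <- config$cord_height * 1e-3             # m
  arc <- sqrt(anchor^2 + u^2)
  lam <- (1 + config$axial_prestrain) * arc / anchor
  sig <- max(uniaxial_nominal_stress(config$pia_material, lam), 0)
  pellet_d <- 2 * sqrt(config$pellet_area / pi)   # mm
  strip_area <- config$pia_thickness * pellet_d * 1e-6  # m^2
  2 * sig * strip_area * (u / arc)
}

#' Reduced-order pellet impact surrogate
#'
#' Integrates a single-degree-of-freedom pellet against a nonlinear
#' viscoelastic foundation: transverse engineering strain is
#' `u / cord_height`, the resisting force combines the QLV nominal cord
#' stress over the pellet area with a pia membrane tension term, and
#' contact is non-adhesive (force clamped at >= 0; the pellet separates on
#' rebound). Time integration is semi-implicit (symplectic) Euler at fixed
#' `dt`. This is an explicitly reduced surrogate for a 3-D impact
#' simulation: only orderings, conservation and round-trip properties are
#' meaningful, not absolute deformations.
#'
#' @param config an [impact_config()].
#' @param dt integration time step in s.
#' @param max_time integration horizon in s.
#' @return A [trajectory()] from impact to pellet separation (or
#'   `max_time`), with an `energy` attribute: a data frame of per-sample
#'   kinetic energy and cumulative contact work (J) for conservation
#'   checks, and a `peak` attribute (mm).
#' @export
simulate_pellet_impact <- function(config, dt = 1e-6, max_time = 0.05) {
  stopifnot(inherits(config, "impact_config"))
  if (dt <= 0) stop("`dt` must be > 0")
  h <- config$cord_height * 1e-3                   # m
  m <- config$pellet_mass
  area_m2 <- config$pellet_area * 1e-6
  prony <- config$cord_material$relaxation
  elastic <- config$cord_material$elastic
  decay <- exp(-prony$beta * dt)
  kern <- prony$g_i * sqrt(decay)
  ginf <- 1 - sum(prony$g_i)

  n_max <- ceiling(max_time / dt) + 1L
  u <- numeric(n_max); v <- numeric(n_max); work <- numeric(n_max)
  kin <- numeric(n_max); f_tr <- numeric(n_max)
  v[1] <- config$impact_velocity
  kin[1] <- 0.5 * m * v[1]^2
  hvars <- numeric(length(prony$g_i))
  sig_e_prev <- 0
  f_prev <- 0
  n_used <- n_max
  for (k in seq_len(n_max - 1L)) {
    eps <- u[k] / h
    if (eps >= 0.99)
      stop("surrogate reached full transverse compression; non-physical configuration")
    # compressive elastic stress (positive in compression), zero out of contact
    sig_e <- if (eps > 0) -uniaxial_nominal_stress(elastic, 1 - eps) else 0
    hvars <- decay * hvars + kern * (sig_e - sig_e_prev)
    sig_e_prev <- sig_e
    sig <- ginf * sig_e + sum(hvars)
    f <- max(sig * area_m2 + .pia_force(config, u[k]), 0)
    if (u[k] <= 0) f <- 0
    f_tr[k] <- f
    v[k + 1L] <- v[k] - f / m * dt
    u[k + 1L] <- u[k] + v[k + 1L] * dt
    work[k + 1L] <- work[k] + f * (u[k + 1L] - u[k])
    kin[k + 1L] <- 0.5 * m * v[k + 1L]^2
    if (u[k + 1L] <= 0 && v[k + 1L] < 0) { n_used <- k + 1L; break }
  }
  idx <- seq_len(n_used)
  u_out <- pmax(u[idx], 0)
  traj <- trajectory((idx - 1L) * dt, u_out * 1e3)
  attr(traj, "energy") <- data.frame(times = (idx - 1L) * dt,
                                     kinetic = kin[idx], work = work[idx])
  attr(traj, "peak") <- max(u_out) * 1e3
  traj
}

#' Pia mater thickness sensitivity sweep
#'
#' Runs the impact surrogate once per pia thickness and tabulates the
#' peak transverse displacement.
#'
#' @param base an [impact_config()]; all fields but `pia_thickness` are held.
#' @param thicknesses numeric vector of pia thicknesses in mm (>= 0).
#' @param dt integration time step in s.
#' @return A data frame with columns `thickness_mm` and `peak_mm`.
#' @export
pia_sensitivity_sweep <- function(base, thicknesses, dt = 1e-6) {
  stopifnot(inherits(base, "impact_config"))
  if (length(thicknesses) < 1L) stop("`thicknesses` must be non-empty")
  if (any(thicknesses < 0)) stop("thicknesses must be >= 0")
  peaks <- vapply(thicknesses, function(th) {
    cfg <- base
    cfg$pia_thickness <- th
    attr(simulate_pellet_impact(cfg, dt = dt), "peak")
  }, 0.0)
  data.frame(thickness_mm = thicknesses, peak_mm = peaks)
}
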