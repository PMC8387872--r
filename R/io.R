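#' Read and write stress-strain curve CSV files
#'
#' The on-disk curve format is a plain CSV with header
#' `strain,stress_pa,rate_per_s` (one curve per file; the rate column is
#' constant). SI units are encoded in the column names.
#'
#' @param curve a [stress_strain_curve()].
#' @param path file path.
#' @param mode loading mode label used when reading.
#' @return `read_curve_csv` returns a [stress_strain_curve()];
#'   `write_curve_csv` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  utils::write.csv(data.frame(strain = curve$strain, stress_pa = curve$stress,
                              rate_per_s = curve$rate),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path, mode = c("compression", "tension")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("strain", "stress_pa", "rate_per_s")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns: ", paste(need, collapse = ", "))
  stress_strain_curve(df$strain, df$stress_pa, df$rate_per_s[1], mode)
}

#' Read and write pellet trajectory CSV files
#'
#' Format: CSV with header `time_s,displacement_mm`.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `read_trajectory_csv` returns a [trajectory()];
#'   `write_trajectory_csv` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(data.frame(time_s = traj$times,
                              displacement_mm = traj$displacements),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "displacement_mm")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  trajectory(df$time_s, df$displacement_mm)
}

#' Reference material parameter sets
#'
#' The fitted continuum material parameters for spinal cord parenchyma
#' (one-term Ogden with three-term normalized Prony relaxation) and pia
#' mater (single-term Ogden), as published for the cord-pia complex:
#' cord mu = 209 Pa, alpha = 7.52, nu = 0.499, G = (0.033, 0.296, 0.406),
#' beta = (2, 13, 406) 1/s; pia mu = 42 kPa, alpha = 12.58, nu = 0.49.
#'
#' @return `reference_cord_material()` returns a [qlv_material()];
#'   `reference_pia_model()` an [ogden_model()].
#' @export
reference_cord_material <- function() {
  qlv_material(ogden_model(mu = 209, alpha = 7.52, poisson_ratio = 0.499),
               prony_series(g_i = c(0.033, 0.296, 0.406), beta = c(2, 13, 406)))
}

#' @rdname reference_cord_material
#' @export
reference_pia_model <- function() {
  ogden_model(mu = 42e3, alpha = 12.58, poisson_ratio = 0.49)
}

#' Circular indenter / pellet contact area
#'
#' Cross-sectional area of a circular indenter or pellet from its
#' diameter: `pi * d^2 / 4`. The 5 mm indentation cylinder gives
#' 19.6 mm^2.
#'
#' @param diameter_mm diameter in mm (> 0).
#' @return Area in mm^2.
#' @export
indenter_area <- function(diameter_mm) {
  if (any(diameter_mm <= 0)) stop("`diameter_mm` must be > 0")
  pi * diameter_mm^2 / 4
}
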