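# Smoothed central-difference velocity of a trajectory (mm/s).
.traj_velocity <- function(traj, k = 5L) {
  u <- traj$displacements; t <- traj$times
  n <- length(u)
  v <- numeric(n)
  v[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- v[2]; v[n] <- v[n - 1]
  if (k > 1L && n > k) {
    kk <- min(k, n - (1 - n %% 2))            # odd window <= n
    if (kk %% 2 == 0) kk <- kk - 1L
    if (kk >= 3L)
      v <- stats::filter(v, rep(1 / kk, kk), sides = 2) |>
        (\(x) { x[is.na(x)] <- v[is.na(x)]; as.numeric(x) })()
  }
  v
}

#' Segment a pellet trajectory into loading, rebound, and unloading phases
#'
#' Labels every sample of an impact trajectory with one of three phases:
#' *loading* runs from first motion until the smoothed velocity falls
#' below `load_frac` (default 20 %) of its early median; *rebound*
#' brackets the displacement maximum until sustained negative velocity;
#' *unloading* is the remainder. Phase-boundary detection is not part of
#' the published procedure; the velocity-threshold rule here is the
#' package's documented choice, with thresholds configurable.
#'
#' @param traj a [trajectory()] with at least 20 samples whose
#'   displacement maximum lies strictly inside the record.
#' @param load_frac velocity fraction of the early median that terminates
#'   the loading phase.
#' @param early_frac fraction of the pre-peak window used to form the
#'   early median velocity.
#' @param neg_run number of consecutive negative-velocity samples that
#'   establish "sustained" rebound exit.
#' @return The trajectory with `phases` filled in and a `boundaries`
#'   attribute (sample indices of the loading end and rebound end).
#' @export
segment_phases <- function(traj, load_frac = 0.2, early_frac = 0.25,
                           neg_run = 3L) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$times)
  if (n < 20L) stop("need at least 20 samples to segment")
  i_peak <- which.max(traj$displacements)
  if (i_peak <= 1L || i_peak >= n)
    stop("no interior displacement maximum: trajectory is not segmentable")
  v <- .traj_velocity(traj)
  early_n <- max(3L, floor(early_frac * i_peak))
  v_early <- stats::median(v[seq_len(early_n)])
  if (v_early <= 0) stop("no initial loading motion detected")
  below <- which(v[seq_len(i_peak)] < load_frac * v_early)
  load_end <- if (length(below)) max(min(below) - 1L, 1L) else i_peak - 1L
  # rebound: from end of loading through the peak until sustained v < 0
  reb_end <- n
  run <- 0L
  for (i in seq(i_peak, n)) {
    run <- if (v[i] < 0) run + 1L else 0L
    if (run >= neg_run) { reb_end <- i - neg_run + 1L; break }
  }
  reb_end <- max(reb_end, i_peak)
  phases <- rep("unloading", n)
  phases[seq_len(load_end)] <- "loading"
  phases[seq(load_end + 1L, reb_end)] <- "rebound"
  out <- trajectory(traj$times, traj$displacements, phases)
  attr(out, "boundaries") <- c(loading_end = load_end, rebound_end = reb_end)
  out
}

# Piecewise polynomial smoothing of a segmented trajectory:
# degree-1 fits on loading and unloading, degree-3 on rebound.
# Continuity across phase boundaries is deliberately not enforced.
.smooth_phases <- function(traj) {
  seg <- if (is.null(traj$phases)) segment_phases(traj) else traj
  out <- seg$displacements
  for (ph in c("loading", "rebound", "unloading")) {
    idx <- which(seg$phases == ph)
    if (length(idx) < 2L) next
    deg <- min(if (ph == "rebound") 3L else 1L, length(idx) - 1L)
    # time normalized to [0, 1] within the phase: raw powers of millisecond
    # scale times are numerically near-collinear
    tt <- seg$times[idx] - seg$times[idx[1]]
    if (max(tt) > 0) tt <- tt / max(tt)
    x_mat <- outer(tt, 0:deg, `^`)
    fit <- stats::lm.fit(x_mat, seg$displacements[idx])
    out[idx] <- x_mat %*% fit$coefficients
  }
  out[1] <- 0  # container convention: records start at zero displacement
  trajectory(seg$times, out, seg$phases)
}

#' Average a set of pellet trajectories
#'
#' Reproduces the published averaging procedure: each trajectory is
#' segmented, the loading and unloading phases are replaced by
#' least-squares linear fits and the rebound phase by a cubic fit
#' (continuity across phase boundaries is not enforced), all smoothed
#' trajectories are resampled onto a common time grid spanning the union
#' of their records, and the pointwise mean is returned.
#'
#' @param trajs list of at least 2 [trajectory()] objects.
#' @param sample_rate common-grid sampling rate in Hz (default 4500, the
#'   rate the experimental trajectories were reported at).
#' @return A [trajectory()] holding the pointwise average. Members that
#'   cannot be segmented are skipped with a warning; if fewer than 2
#'   remain, an error is raised.
#' @export
average_trajectories <- function(trajs, sample_rate = 4500) {
  if (length(trajs) < 2L) stop("need at least 2 trajectories")
  smoothed <- list()
  for (i in seq_along(trajs)) {
    s <- tryCatch(.smooth_phases(trajs[[i]]), error = function(e) {
      warning(sprintf("trajectory %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(s)) smoothed[[length(smoothed) + 1L]] <- s
  }
  if (length(smoothed) < 2L) stop("fewer than 2 segmentable trajectories")
  t_max <- max(vapply(smoothed, function(s) max(s$times), 0.0))
  grid <- seq(0, t_max, by = 1 / sample_rate)
  mat <- vapply(smoothed, function(s)
    stats::approx(s$times, s$displacements, xout = grid)$y,
    numeric(length(grid)))
  avg <- rowMeans(mat, na.rm = TRUE)
  avg[is.nan(avg)] <- 0
  avg[1] <- 0
  trajectory(grid, avg)
}

#' Summarize a pellet trajectory
#'
#' Extracts the scalar descriptors used to compare impacts: peak
#' deformation, time to peak from first motion, and the initial pellet
#' velocity estimated as the slope of a linear fit to the first portion
#' of the loading phase (the published procedure for recovering pellet
#' velocity from trajectory data).
#'
#' @param traj a segmentable [trajectory()].
#' @param velocity_frac fraction of the loading-phase samples used for the
#'   initial-velocity slope fit (default the first 25 %).
#' @return A list of class `trajectory_summary`: `peak_mm`,
#'   `time_to_peak_ms`, `initial_velocity_ms` (m/s), and `boundaries_s`
#'   (loading end, rebound end).
#' @export
summarize_trajectory <- function(traj, velocity_frac = 0.25) {
  seg <- if (is.null(traj$phases)) segment_phases(traj) else traj
  b <- attr(seg, "boundaries")
  if (is.null(b)) { seg <- segment_phases(trajectory(seg$times, seg$displacements))
                    b <- attr(seg, "boundaries") }
  i_peak <- which.max(seg$displacements)
  moving <- which(seg$displacements > 0)
  i0 <- if (length(moving)) max(moving[1] - 1L, 1L) else 1L
  load_idx <- seq_len(b[["loading_end"]])
  load_idx <- load_idx[load_idx >= i0]
  k <- max(2L, ceiling(velocity_frac * length(load_idx)))
  idx <- load_idx[seq_len(min(k, length(load_idx)))]
  sl <- stats::coef(stats::lm(seg$displacements[idx] ~ seg$times[idx]))[2]
  structure(list(peak_mm = max(seg$displacements),
                 time_to_peak_ms = (seg$times[i_peak] - seg$times[i0]) * 1e3,
                 initial_velocity_ms = as.numeric(sl) / 1e3,
                 boundaries_s = seg$times[b]),
            class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("peak %.3g mm at %.3g ms; initial velocity %.3g m/s\n",
              x$peak_mm, x$time_to_peak_ms, x$initial_velocity_ms))
  invisible(x)
}
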