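#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - RSS/TSS} with
#' \eqn{RSS = \sum (y_i - \hat y_i)^2} and
#' \eqn{TSS = \sum (y_i - \bar y)^2}. Bounded above by 1, can be negative
#' when the prediction is worse than the observed mean.
#'
#' @param observed numeric vector of observations (not constant).
#' @param predicted numeric vector of model predictions, same length.
#' @return Scalar R-squared.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) < 2L || length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length >= 2")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("R-squared undefined for constant `observed`")
  1 - sum((observed - predicted)^2) / tss
}

#' Root-mean-square error
#'
#' @param observed numeric vector.
#' @param predicted numeric vector, same length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) < 1L || length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length >= 1")
  sqrt(mean((observed - predicted)^2))
}

# Resample two (x, y) signals onto a common uniform grid over the overlap
# of their supports. Returns list(x, y_ref, y_cand).
.common_grid <- function(x_ref, y_ref, x_cand, y_cand, n = 400L) {
  lo <- max(min(x_ref), min(x_cand))
  hi <- min(max(x_ref), max(x_cand))
  if (hi <= lo) stop("signals have no overlapping support")
  xx <- seq(lo, hi, length.out = n)
  list(x = xx,
       y_ref = stats::approx(x_ref, y_ref, xout = xx)$y,
       y_cand = stats::approx(x_cand, y_cand, xout = xx)$y)
}

.as_signal <- function(obj) {
  if (inherits(obj, "trajectory")) list(x = obj$times, y = obj$displacements)
  else if (inherits(obj, "stress_strain_curve")) list(x = obj$strain, y = obj$stress)
  else if (is.list(obj) && all(c("x", "y") %in% names(obj))) obj
  else stop("expected a trajectory, stress_strain_curve, or list(x, y)")
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Two-component CORA curve-correlation rating
#'
#' Simplified CORrelation and Analysis rating with equally weighted size
#' and shape components (weights 0.5/0.5). The size rating compares the
#' areas under the two curves on their common window,
#' `min(A_ref, A_cand) / max(A_ref, A_cand)` with \eqn{A = \int |y| dx};
#' the shape rating is the maximum, over time shifts within +/-10 % of the
#' window, of the normalized cross-correlation of the two derivative
#' signals, clamped to `[0, 1]`. Statistical corridors and sub-interval
#' weighting of the full CORA method are not implemented.
#'
#' @param reference,candidate [trajectory()], [stress_strain_curve()], or
#'   `list(x, y)` signals with overlapping support.
#' @param shift_frac half-width of the admissible shift window as a
#'   fraction of the common window length.
#' @return A list of class `cora_result` with `size`, `shape`, `total`
#'   (all in `[0, 1]`) and `weights = c(0.5, 0.5)`.
#' @export
cora_rating <- function(reference, candidate, shift_frac = 0.1) {
  ref <- .as_signal(reference); cand <- .as_signal(candidate)
  g <- .common_grid(ref$x, ref$y, cand$x, cand$y)
  a_ref <- .trapz(g$x, abs(g$y_ref)); a_cand <- .trapz(g$x, abs(g$y_cand))
  size <- if (a_ref == 0 && a_cand == 0) 1
          else if (max(a_ref, a_cand) == 0) 0
          else min(a_ref, a_cand) / max(a_ref, a_cand)
  d_ref <- diff(g$y_ref); d_cand <- diff(g$y_cand)
  max_shift <- max(1L, floor(shift_frac * length(d_ref)))
  best <- -1
  for (s in seq(-max_shift, max_shift)) {
    if (s >= 0) { a <- d_ref[seq_len(length(d_ref) - s)]; b <- d_cand[seq_len(length(d_cand) - s) + s] }
    else        { a <- d_ref[seq_len(length(d_ref) + s) - s]; b <- d_cand[seq_len(length(d_cand) + s)] }
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    r <- if (na == 0 && nb == 0) 1 else if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    if (r > best) best <- r
  }
  shape <- min(max(best, 0), 1)
  structure(list(size = size, shape = shape,
                 total = 0.5 * size + 0.5 * shape, weights = c(0.5, 0.5)),
            class = "cora_result")
}

#' @export
print.cora_result <- function(x, ...) {
  cat(sprintf("CORA rating: size %.3f, shape %.3f, total %.3f (weights 0.5/0.5)\n",
              x$size, x$shape, x$total))
  invisible(x)
}

#' Richardson extrapolation from three systematically refined meshes
#'
#' Given solutions `f1, f2, f3` on meshes `h1 > h2 > h3` with a constant
#' refinement ratio `r = h1/h2 = h2/h3`, estimates the observed order of
#' convergence \eqn{p = \ln|(f_1 - f_2)/(f_2 - f_3)| / \ln r} and the
#' zero-mesh-size solution \eqn{f_3 + (f_3 - f_2)/(r^p - 1)}. Oscillatory
#' convergence (a sign change between successive differences) is flagged
#' and the extrapolation withheld; identical values yield a degenerate
#' result with the extrapolated value equal to `f3`.
#'
#' @param mesh_sizes numeric vector `c(h1, h2, h3)` with `h1 > h2 > h3 > 0`
#'   and constant refinement ratio within 1 %.
#' @param values numeric vector `c(f1, f2, f3)` of the corresponding
#'   solutions.
#' @return A list of class `richardson_result` with `order`,
#'   `extrapolated`, `percent_differences` (between successive meshes),
#'   `asymptotic` (logical), and `degenerate`/`oscillatory` flags.
#' @export
richardson_extrapolate <- function(mesh_sizes, values) {
  if (length(mesh_sizes) != 3L || length(values) != 3L)
    stop("need exactly three mesh sizes and three values")
  h <- as.numeric(mesh_sizes); f <- as.numeric(values)
  if (any(h <= 0) || is.unsorted(rev(h), strictly = TRUE))
    stop("`mesh_sizes` must satisfy h1 > h2 > h3 > 0")
  r1 <- h[1] / h[2]; r2 <- h[2] / h[3]
  if (abs(r1 / r2 - 1) > 0.01)
    stop("refinement ratio must be constant within 1%")
  r <- sqrt(r1 * r2)
  d12 <- f[1] - f[2]; d23 <- f[2] - f[3]
  pct <- abs(diff(f)) / abs(f[-1]) * 100
  if (d12 == 0 && d23 == 0)
    return(structure(list(order = NA_real_, extrapolated = f[3],
                          percent_differences = pct, asymptotic = FALSE,
                          degenerate = TRUE, oscillatory = FALSE),
                     class = "richardson_result"))
  if (d23 == 0 || d12 * d23 < 0)
    return(structure(list(order = NA_real_, extrapolated = NA_real_,
                          percent_differences = pct, asymptotic = FALSE,
                          degenerate = d23 == 0, oscillatory = d12 * d23 < 0),
                     class = "richardson_result"))
  p <- log(abs(d12 / d23)) / log(r)
  extrap <- f[3] + (f[3] - f[2]) / (r^p - 1)
  structure(list(order = p, extrapolated = extrap,
                 percent_differences = pct,
                 asymptotic = is.finite(p) && p > 0,
                 degenerate = FALSE, oscillatory = FALSE),
            class = "richardson_result")
}

#' @export
print.richardson_result <- function(x, ...) {
  if (isTRUE(x$oscillatory)) {
    cat("Richardson extrapolation: oscillatory convergence, extrapolation withheld\n")
  } else if (isTRUE(x$degenerate)) {
    cat(sprintf("Richardson extrapolation: degenerate (constant values), limit %.6g\n",
                x$extrapolated))
  } else {
    cat(sprintf("Richardson extrapolation: observed order %.4g, limit %.6g\n",
                x$order, x$extrapolated))
  }
  cat(sprintf("  successive differences: %s %%\n",
              paste(sprintf("%.3g", x$percent_differences), collapse = ", ")))
  invisible(x)
}
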