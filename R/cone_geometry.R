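#' Cone trajectory parameters
#'
#' Bundle of the free parameters of the two-stage parametric cone: the cone
#' half-angle `theta` (degrees) spanned by the trajectory endpoint and the
#' central axis, the stage separation point `m` along the curve parameter,
#' the curvature power `n`, the azimuthal twist scaling `A` (radians of
#' azimuthal sweep over the whole curve), the maximum spatial frequency
#' `k_max` (1/mm), and the target readout duration (ms). Setting `m = 0`
#' gives the single-stage design (pure `alpha^n` radial law); `theta = 0`
#' degenerates to a straight radial spoke.
#'
#' @param theta cone half-angle in degrees, in `[0, 90)`.
#' @param m stage separation point, in `[0, 1]`.
#' @param n curvature power, `>= 1`.
#' @param A twist scaling factor (radians), `>= 0`.
#' @param k_max maximum spatial frequency (1/mm), `> 0`. Nominal isotropic
#'   resolution is `1/(2*k_max)` mm.
#' @param readout_duration target readout duration in ms, `> 0`.
#' @return an object of class `cone_params`.
#' @export
cone_params <- function(theta, m, n, A = 0, k_max, readout_duration) {
  if (!is.numeric(theta) || theta < 0 || theta >= 90)
    stop_field("theta", "must be in [0, 90) degrees")
  if (!is.numeric(m) || m < 0 || m > 1)
    stop_field("m", "must be in [0, 1]")
  if (!is.numeric(n) || n < 1)
    stop_field("n", "must be >= 1")
  if (!is.numeric(A) || A < 0)
    stop_field("A", "must be >= 0")
  if (!is.numeric(k_max) || k_max <= 0 || !is.finite(k_max))
    stop_field("k_max", "must be a positive finite spatial frequency (1/mm)")
  if (!is.numeric(readout_duration) || readout_duration <= 0)
    stop_field("readout_duration", "must be a positive duration (ms)")
  structure(list(theta = theta, m = m, n = n, A = A, k_max = k_max,
                 readout_duration = readout_duration),
            class = "cone_params")
}

#' @export
print.cone_params <- function(x, ...) {
  cat(sprintf(
    "cone_params: theta=%.4g deg, m=%.4g, n=%.4g, A=%.6g rad, k_max=%.6g /mm (%.4g mm res), readout=%.4g ms\n",
    x$theta, x$m, x$n, x$A, x$k_max, 1 / (2 * x$k_max), x$readout_duration))
  invisible(x)
}

#' k_max for a nominal isotropic resolution
#'
#' @param resolution_mm nominal isotropic resolution in mm.
#' @return maximum spatial frequency in 1/mm (`1/(2*resolution)`).
#' @export
kmax_for_resolution <- function(resolution_mm) {
  if (resolution_mm <= 0) stop_field("resolution_mm", "must be positive")
  1 / (2 * resolution_mm)
}

#' Generate the two-stage base cone curve
#'
#' Evaluates the base cone at `num_samples` uniformly spaced values of the
#' curve parameter `alpha` in `(0, 1]`, in a frame whose third basis vector
#' is the cone axis. Stage 1 (`alpha <= m`) is a conventional cone of fixed
#' half-angle `arctan(m^(n-1) tan(theta))`: axial component
#' `k_max cos(theta) alpha`, transverse radius `m^(n-1) k_max sin(theta)
#' alpha`, azimuth `A alpha`. Stage 2 (`alpha > m`) lets the cone angle grow
#' with radius: transverse radius `k_max sin(theta) alpha^n`, same axial and
#' azimuthal laws. The two branches agree at `alpha = m`, the curve starts
#' at the k-space origin and ends at magnitude `k_max` at angle `theta`
#' from the axis.
#'
#' @param params a [cone_params()] object.
#' @param num_samples number of alpha samples (`>= 2`).
#' @return an object of class `base_cone_curve` with fields `alpha`
#'   (samples in (0, 1]), `points` (num_samples x 3, 1/mm), `basis` (3 x 3
#'   identity: columns kx, ky, kz with kz the cone axis), and `params`.
#' @export
base_cone <- function(params, num_samples) {
  stopifnot(inherits(params, "cone_params"))
  if (!is.numeric(num_samples) || num_samples < 2)
    stop_field("num_samples", "must be >= 2")
  alpha <- seq_len(num_samples) / num_samples
  pts <- cone_points(params, alpha)
  structure(list(alpha = alpha, points = pts, basis = diag(3),
                 params = params),
            class = "base_cone_curve")
}

# Evaluate Eq. (two-branch cone law) at arbitrary alpha in (0, 1].
cone_points <- function(params, alpha) {
  th <- deg2rad(params$theta)
  m <- params$m; n <- params$n; A <- params$A; kmax <- params$k_max
  r <- ifelse(alpha <= m & m > 0,
              m^(n - 1) * kmax * sin(th) * alpha,
              kmax * sin(th) * alpha^n)
  cbind(kx = r * cos(A * alpha),
        ky = r * sin(A * alpha),
        kz = kmax * cos(th) * alpha)
}

#' Constant half-angle of the stage-1 cone
#'
#' The first stage of the two-stage design is a conventional fixed-angle
#' cone; its half-angle is `arctan(m^(n-1) tan(theta))`.
#'
#' @param params a [cone_params()] with `m > 0`.
#' @return the stage-1 half-angle in degrees.
#' @export
stage1_cone_angle <- function(params) {
  stopifnot(inherits(params, "cone_params"))
  if (params$m <= 0)
    stop("stage 1 is undefined for m = 0 (single-stage design)", call. = FALSE)
  rad2deg(atan(params$m^(params$n - 1) * tan(deg2rad(params$theta))))
}

#' Solve the twist scaling for a target readout duration
#'
#' The twist factor `A` controls how much azimuthal winding the cone carries:
#' larger `A` means a longer path and hence a longer time-optimal traversal
#' under fixed hardware limits. This routine finds `A` such that the
#' time-optimal waveform duration (via [time_optimal_waveform()]) matches
#' `params$readout_duration`, by bracketing (duration is non-decreasing in
#' `A`) and bisection to the requested relative tolerance.
#'
#' @param params a [cone_params()]; its `A` field is ignored.
#' @param limits a [hardware_limits()] object.
#' @param tol relative duration tolerance (default 0.005).
#' @param num_samples geometry sampling density used during the search.
#' @return the solved `A` (radians), with attribute `duration_ms` giving the
#'   achieved time-optimal duration.
#' @export
solve_twist_scaling <- function(params, limits, tol = 0.005,
                                num_samples = 2000) {
  stopifnot(inherits(params, "cone_params"), inherits(limits, "hardware_limits"))
  target <- params$readout_duration
  dur_of <- function(A) {
    p <- params; p$A <- A
    w <- time_optimal_waveform(base_cone(p, cone_num_samples(A, num_samples)),
                               limits)
    attr(w, "duration_ms") %||% max(w$t)
  }
  d0 <- dur_of(0)
  if (d0 > target * (1 + tol))
    stop(sprintf(
      "infeasible readout duration: %.4g ms requested but the A = 0 minimum is %.4g ms",
      target, d0), call. = FALSE)
  if (abs(d0 - target) <= tol * target)
    return(structure(0, duration_ms = d0))
  # bracket: duration is non-decreasing in A
  lo <- 0; hi <- max(2 * pi, 1)
  dhi <- dur_of(hi)
  while (dhi < target && hi < 1e5) {
    lo <- hi; hi <- 2 * hi
    dhi <- dur_of(hi)
  }
  if (dhi < target)
    stop("could not bracket the requested duration; target too long", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    dm <- dur_of(mid)
    if (abs(dm - target) <= tol * target) {
      return(structure(mid, duration_ms = dm))
    }
    if (dm < target) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  structure(mid, duration_ms = dur_of(mid))
}

#' Design a cone readout end-to-end
#'
#' Convenience wrapper: solves the twist scaling for the requested readout
#' duration, then returns the final curve and time-optimal waveform.
#'
#' @inheritParams solve_twist_scaling
#' @param num_samples base geometry sampling density for the final curve.
#' @return list with `params` (A filled in), `curve`, `waveform`.
#' @export
design_cone <- function(params, limits, tol = 0.005, num_samples = 2000) {
  A <- solve_twist_scaling(params, limits, tol = tol,
                           num_samples = num_samples)
  p <- params; p$A <- as.numeric(A)
  curve <- base_cone(p, cone_num_samples(p$A, num_samples))
  wave <- time_optimal_waveform(curve, limits)
  list(params = p, curve = curve, waveform = wave)
}

# geometry density that resolves the azimuthal twist: at least `base`
# alpha samples and ~250 per radian of total twist
cone_num_samples <- function(A, base = 2000) {
  max(base, ceiling(250 * A))
}
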