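#' Protocol timing parameters
#'
#' Timing of the continuous readout train that follows each ASL preparation:
#' repetition time `tr`, total train duration, and (optionally) a per-TR
#' flip-angle schedule carried as data. The number of readouts per
#' preparation `n_tr = train_duration / tr` must be a whole number.
#'
#' @param tr repetition time between excitations (ms).
#' @param train_duration total readout train duration after each
#'   preparation (ms).
#' @param readout_time per-shot ADC duration (ms).
#' @param flip_schedule optional numeric vector of per-TR flip angles
#'   (degrees); data only, no optimization is performed.
#' @return an object of class `protocol_params` with derived field `n_tr`.
#' @export
protocol_params <- function(tr, train_duration, readout_time = NA_real_,
                            flip_schedule = NULL) {
  if (tr <= 0) stop_field("tr", "must be positive (ms)")
  if (train_duration <= 0) stop_field("train_duration", "must be positive (ms)")
  ratio <- train_duration / tr
  n_tr <- round(ratio)
  if (abs(ratio - n_tr) > 1e-9 * max(1, ratio))
    stop_field("train_duration",
               sprintf("train/tr = %.6f is not a whole number of readouts", ratio))
  if (!is.null(flip_schedule) && length(flip_schedule) != n_tr)
    stop_field("flip_schedule", "length must equal n_tr")
  structure(list(tr = tr, train_duration = train_duration,
                 readout_time = readout_time, n_tr = as.integer(n_tr),
                 flip_schedule = flip_schedule),
            class = "protocol_params")
}

# 2D golden means driving the 3D golden-ratio axis sequence
# (the two quadratic irrationals from the modified Fibonacci lattice).
GOLDEN_MEAN_1 <- 0.4656105901262136
GOLDEN_MEAN_2 <- 0.6823278038280193

#' Axis of the i-th shot under 3D golden-ratio ordering
#'
#' The unit axis is built from two golden-mean increments: the z component
#' is `2*frac(i*phi1) - 1` (covering the full sphere) and the azimuth is
#' `2*pi*frac(i*phi2)`, with `phi1 = 0.46561...`, `phi2 = 0.68233...`.
#' Any contiguous run of indices covers the sphere near-uniformly, which is
#' what makes post-hoc temporal binning of shots well conditioned.
#'
#' @param i non-negative integer index (vectorized).
#' @return length(i) x 3 matrix of unit axis vectors.
#' @export
golden_axis <- function(i) {
  if (any(i < 0)) stop_field("i", "indices must be non-negative")
  z <- 2 * ((i * GOLDEN_MEAN_1) %% 1) - 1
  az <- 2 * pi * ((i * GOLDEN_MEAN_2) %% 1)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(az), y = r * sin(az), z = z)
}

# rotation taking the +z axis onto unit vector a (Rodrigues)
rotation_z_to <- function(a) {
  z <- c(0, 0, 1)
  c_ <- a[3]
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  s2 <- sum(v^2)
  if (s2 < 1e-24) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))               # 180 deg about x
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

rotation_about_z <- function(psi) {
  matrix(c(cos(psi), sin(psi), 0, -sin(psi), cos(psi), 0, 0, 0, 1), 3, 3)
}

#' Build the full shot schedule
#'
#' Assigns every shot of a multi-repeat readout train its rotation. The shot
#' acquired at repeat `r` (0-based) and TR index `t` receives golden index
#' `i = t * n_repeats + r` -- the golden-ratio rotation is incremented first
#' across repeats and then across time, so that grouping all repeats of any
#' contiguous TR window yields a contiguous (hence near-uniform) golden-ratio
#' set. The base cone axis (+z) is rotated onto [golden_axis()]`(i)` and the
#' cone is additionally spun about its own axis by a seeded uniform random
#' angle, which decorrelates the azimuthal twist of overlapping cones.
#'
#' @param protocol a [protocol_params()] object.
#' @param n_repeats number of preparations (repeats) per condition.
#' @param seed integer RNG seed for the random spin angles.
#' @return an object of class `shot_schedule`: data frame `shots` with
#'   columns `shot`, `repeat_idx`, `tr_idx`, `golden_index`, `spin_angle`,
#'   `t_start_ms`; list `rotations` of 3x3 matrices; plus `n_repeats`,
#'   `n_tr`, `protocol`, `seed`.
#' @export
build_schedule <- function(protocol, n_repeats, seed = 1L) {
  stopifnot(inherits(protocol, "protocol_params"))
  if (n_repeats < 1) stop_field("n_repeats", "must be >= 1")
  n_tr <- protocol$n_tr
  S <- n_repeats * n_tr
  rep_idx <- rep(0:(n_repeats - 1), times = n_tr)
  tr_idx <- rep(0:(n_tr - 1), each = n_repeats)
  gi <- tr_idx * n_repeats + rep_idx
  axes <- golden_axis(gi)
  rng <- local({ set.seed(seed); runif(S, 0, 2 * pi) })
  rotations <- lapply(seq_len(S), function(s)
    rotation_z_to(axes[s, ]) %*% rotation_about_z(rng[s]))
  shots <- data.frame(shot = seq_len(S) - 1L, repeat_idx = rep_idx,
                      tr_idx = tr_idx, golden_index = gi,
                      spin_angle = rng,
                      t_start_ms = tr_idx * protocol$tr)
  structure(list(shots = shots, rotations = rotations,
                 n_repeats = as.integer(n_repeats), n_tr = n_tr,
                 protocol = protocol, seed = as.integer(seed)),
            class = "shot_schedule")
}

#' @export
print.shot_schedule <- function(x, ...) {
  cat(sprintf("shot_schedule: %d shots (%d repeats x %d TRs), tr = %.4g ms, seed = %d\n",
              nrow(x$shots), x$n_repeats, x$n_tr, x$protocol$tr, x$seed))
  invisible(x)
}

#' Rotate base-shot samples through a schedule
#'
#' @param schedule a [build_schedule()] result.
#' @param base_k S0 x 3 matrix of one shot's k-space samples (1/mm), in the
#'   base frame (cone axis along +z).
#' @param shots optional subset of shot numbers (0-based); default all.
#' @return (length(shots) * S0) x 3 matrix of rotated samples, ordered shot
#'   by shot, with attribute `shot` giving each row's shot number.
#' @export
rotate_samples <- function(schedule, base_k, shots = NULL) {
  stopifnot(inherits(schedule, "shot_schedule"))
  base_k <- as_kmat(base_k)
  shots <- shots %||% schedule$shots$shot
  out <- do.call(rbind, lapply(shots, function(s)
    base_k %*% t(schedule$rotations[[s + 1]])))
  colnames(out) <- c("kx", "ky", "kz")
  attr(out, "shot") <- rep(shots, each = nrow(base_k))
  out
}

#' Bin shots into temporal frames with an optional k-space radius cut
#'
#' Groups shots (across all repeats) whose TR start time falls inside each
#' consecutive window of `temporal_window` ms; within each frame only
#' samples with `|k| <= k_radius_fraction * k_max` are retained. Because
#' rotations preserve `|k|`, the radial cut is a single per-sample mask
#' shared by all shots. With `half_shots = TRUE` only the first half of the
#' repeats contributes to each frame (the angiographic convention of using
#' half the shots of the window).
#'
#' @param schedule a [build_schedule()] result.
#' @param base_k one shot's base-frame samples (S0 x 3, 1/mm).
#' @param temporal_window frame width (ms); should divide the train
#'   duration (tolerance 1e-6) unless `allow_truncation = TRUE`.
#' @param k_radius_fraction fraction of `k_max` retained, in (0, 1].
#' @param half_shots use only the first half of the repeats per frame.
#' @param allow_truncation permit a window that does not divide the train
#'   (trailing shots beyond the last full frame are dropped).
#' @return an object of class `frame_binning`: `frames` (list; each has
#'   `shots`, 0-based shot numbers, and `t_range`), `sample_keep` (logical
#'   mask over the S0 base samples), `n_frames`, `temporal_window`,
#'   `k_radius_fraction`, `k_max`.
#' @export
bin_frames <- function(schedule, base_k, temporal_window,
                       k_radius_fraction = 1, half_shots = FALSE,
                       allow_truncation = FALSE) {
  stopifnot(inherits(schedule, "shot_schedule"))
  base_k <- as_kmat(base_k)
  if (k_radius_fraction <= 0 || k_radius_fraction > 1)
    stop_field("k_radius_fraction", "must be in (0, 1]")
  train <- schedule$protocol$train_duration
  if (temporal_window <= 0) stop_field("temporal_window", "must be positive (ms)")
  if (temporal_window > train + 1e-9) {
    warning("temporal window exceeds the readout train; using a single frame")
    temporal_window <- train
  }
  ratio <- train / temporal_window
  if (abs(ratio - round(ratio)) > 1e-6 * ratio && !allow_truncation)
    stop_field("temporal_window",
               "does not divide the train duration; set allow_truncation = TRUE to drop the remainder")
  n_frames <- as.integer(floor(train / temporal_window + 1e-9))
  radii <- sqrt(rowSums(base_k^2))
  k_max <- max(radii)
  keep <- radii <= k_radius_fraction * k_max + 1e-12
  rep_keep <- if (half_shots) {
    schedule$shots$repeat_idx < schedule$n_repeats / 2
  } else rep(TRUE, nrow(schedule$shots))
  frames <- lapply(seq_len(n_frames) - 1L, function(f) {
    t0 <- f * temporal_window; t1 <- (f + 1) * temporal_window
    sel <- schedule$shots$t_start_ms >= t0 - 1e-9 &
      schedule$shots$t_start_ms < t1 - 1e-9 & rep_keep
    list(shots = schedule$shots$shot[sel], t_range = c(t0, t1))
  })
  structure(list(frames = frames, sample_keep = keep,
                 n_frames = n_frames, temporal_window = temporal_window,
                 k_radius_fraction = k_radius_fraction, k_max = k_max),
            class = "frame_binning")
}

#' Frame-wise rotated sample positions
#'
#' @param schedule a [build_schedule()] result.
#' @param base_k one shot's base-frame samples.
#' @param binning a [bin_frames()] result for the same base samples.
#' @return list (one element per frame) of k-sample matrices after rotation
#'   and the radial cut.
#' @export
frame_samples <- function(schedule, base_k, binning) {
  base_k <- as_kmat(base_k)
  bk <- base_k[binning$sample_keep, , drop = FALSE]
  lapply(binning$frames, function(fr)
    rotate_samples(schedule, bk, shots = fr$shots))
}

#' Protocol arithmetic summary
#'
#' Pure arithmetic consistency report for a protocol: readouts per
#' preparation, train duration, frame counts at the given temporal windows,
#' and nominal resolutions at the given k-space radius fractions (nominal
#' resolution at fraction `f` is `1/(2*k_max)/f`).
#'
#' @param protocol a [protocol_params()] object.
#' @param windows temporal windows (ms) at which to report frame counts.
#' @param k_max maximum spatial frequency (1/mm), for the resolution report
#'   (optional).
#' @param radius_fractions k-space radius fractions for the resolution
#'   report.
#' @return list with `n_tr`, `train_duration`, `frame_counts` (named by
#'   window), and `nominal_resolution_mm` (named by fraction; `NULL` if
#'   `k_max` missing).
#' @export
protocol_arithmetic <- function(protocol, windows = numeric(0), k_max = NULL,
                                radius_fractions = 1) {
  stopifnot(inherits(protocol, "protocol_params"))
  fc <- if (length(windows))
    stats::setNames(floor(protocol$train_duration / windows + 1e-9),
                    paste0(windows, "ms")) else NULL
  res <- if (!is.null(k_max))
    stats::setNames((1 / (2 * k_max)) / radius_fractions,
                    paste0("f=", signif(radius_fractions, 4))) else NULL
  list(n_tr = protocol$n_tr, train_duration = protocol$train_duration,
       frame_counts = fc, nominal_resolution_mm = res)
}
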