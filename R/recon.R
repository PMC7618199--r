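#' Assemble a multi-frame reconstruction problem
#'
#' Bundles, per temporal frame, the acquired multi-coil data `y`, the
#' non-uniform Fourier encoding (a [nufft_plan()] holding the retained
#' sample positions), and the shared coil sensitivity maps `C`. This is the
#' object both [adjoint_recon()] and [llr_recon()] consume.
#'
#' @param plans list of [nufft_plan()] objects, one per frame (all on the
#'   same image grid).
#' @param y list of complex C x S_f matrices, one per frame.
#' @param coil_maps complex (nx, ny, nz, C) sensitivity array, or `NULL`
#'   for a single uniform coil.
#' @return an object of class `recon_problem`.
#' @export
recon_problem <- function(plans, y, coil_maps = NULL) {
  stopifnot(length(plans) == length(y), length(plans) >= 1)
  N <- plans[[1]]$N
  for (f in seq_along(plans)) {
    stopifnot(inherits(plans[[f]], "nufft_plan"))
    if (!identical(plans[[f]]$N, N))
      stop_field("plans", "all frames must share one image grid")
    yf <- y[[f]]
    if (!is.matrix(yf) || ncol(yf) != plans[[f]]$n_samples)
      stop_field("y", sprintf("frame %d: data must be C x %d", f,
                              plans[[f]]$n_samples))
  }
  n_coils <- nrow(y[[1]])
  if (!is.null(coil_maps)) {
    stopifnot(length(dim(coil_maps)) == 4, dim(coil_maps)[4] == n_coils,
              identical(as.integer(dim(coil_maps)[1:3]), as.integer(N)))
  }
  structure(list(plans = plans, y = y, coil_maps = coil_maps,
                 n_frames = length(plans), n_coils = n_coils, N = N),
            class = "recon_problem")
}

# forward / adjoint of the frame encoding A_f = P F C
frame_forward <- function(prob, f, x) {
  plan <- prob$plans[[f]]
  out <- matrix(0 + 0i, prob$n_coils, plan$n_samples)
  for (c_ in seq_len(prob$n_coils)) {
    xc <- if (is.null(prob$coil_maps)) x else x * prob$coil_maps[, , , c_]
    out[c_, ] <- nufft_forward(plan, xc)
  }
  out
}

frame_adjoint <- function(prob, f, y) {
  plan <- prob$plans[[f]]
  acc <- array(0 + 0i, dim = prob$N)
  for (c_ in seq_len(prob$n_coils)) {
    a <- nufft_adjoint(plan, as.complex(y[c_, ]))
    acc <- acc + if (is.null(prob$coil_maps)) a else
      Conj(prob$coil_maps[, , , c_]) * a
  }
  acc
}

#' Density-compensated adjoint reconstruction
#'
#' Per frame: optional radial Hann apodization of the data, density-weighted
#' adjoint NUFFT per coil, then coil combination by the conjugate-sensitivity
#' sum normalized by `sum |C|^2` (a plain average for uniform maps).
#'
#' @param prob a [recon_problem()].
#' @param weights list of per-frame density weights; computed via
#'   [density_compensation()] when `NULL`.
#' @param hann apply radial Hann apodization to the data first.
#' @return complex 4D array (nx, ny, nz, n_frames).
#' @export
adjoint_recon <- function(prob, weights = NULL, hann = FALSE) {
  stopifnot(inherits(prob, "recon_problem"))
  if (is.null(weights))
    weights <- lapply(prob$plans, density_compensation)
  out <- array(0 + 0i, dim = c(prob$N, prob$n_frames))
  for (f in seq_len(prob$n_frames)) {
    plan <- prob$plans[[f]]
    w <- weights[[f]]
    if (length(w) != plan$n_samples)
      stop_field("weights", "per-frame weight length must match the samples")
    if (hann) w <- w * hann_weights(plan$k)
    num <- array(0 + 0i, dim = prob$N); den <- 0
    for (c_ in seq_len(prob$n_coils)) {
      a <- nufft_adjoint(plan, as.complex(prob$y[[f]][c_, ] * w))
      if (is.null(prob$coil_maps)) {
        num <- num + a; den <- den + 1
      } else {
        num <- num + Conj(prob$coil_maps[, , , c_]) * a
        den <- den + abs(prob$coil_maps[, , , c_])^2
      }
    }
    out[, , , f] <- num / pmax(den, 1e-12)
  }
  out
}

#' Locally-low-rank reconstruction settings
#'
#' @param lam regularization weight lambda (default 0.1); interpreted on
#'   data normalized so the unweighted adjoint image has unit peak
#'   magnitude, which makes the value transferable across data scales.
#' @param patch cubic patch edge in voxels (default 5).
#' @param max_iter iteration cap (default 200).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param seed seed for the random cyclic patch tiling offset.
#' @param cycle_spin redraw the tiling offset every iteration (suppresses
#'   blocking artifacts at patch boundaries, at the cost of the recorded
#'   objective being only approximately monotone since the regularizer's
#'   tiling changes between iterations). Default `FALSE`: one seeded
#'   random offset is drawn per solve, giving a single well-defined
#'   objective that decreases monotonically.
#' @return an object of class `llr_config`.
#' @export
llr_config <- function(lam = 0.1, patch = 5, max_iter = 200, tol = 1e-6,
                       seed = 1L, cycle_spin = FALSE) {
  if (lam < 0) stop_field("lam", "must be >= 0")
  if (patch < 1) stop_field("patch", "must be >= 1")
  if (max_iter < 1) stop_field("max_iter", "must be >= 1")
  structure(list(lam = lam, patch = as.integer(patch),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), cycle_spin = isTRUE(cycle_spin)),
            class = "llr_config")
}

# pad 4D array spatial dims (zero) to multiples of p after a cyclic shift
shift_pad <- function(x4, shift, p) {
  N <- dim(x4)[1:3]
  idx <- lapply(1:3, function(d) ((seq_len(N[d]) - 1 + shift[d]) %% N[d]) + 1L)
  xs <- x4[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  Np <- as.integer(ceiling(N / p) * p)
  if (all(Np == N)) return(xs)
  out <- array(0 + 0i, dim = c(Np, dim(x4)[4]))
  out[1:N[1], 1:N[2], 1:N[3], ] <- xs
  out
}

unshift_crop <- function(xp, shift, N) {
  xs <- xp[1:N[1], 1:N[2], 1:N[3], , drop = FALSE]
  idx <- lapply(1:3, function(d) ((seq_len(N[d]) - 1 - shift[d]) %% N[d]) + 1L)
  xs[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
}

# patch-wise SVT (tau > 0) or nuclear-norm evaluation (tau = NULL)
llr_patch_pass <- function(x4, p, shift, tau = NULL) {
  N <- dim(x4)[1:3]; Tn <- dim(x4)[4]
  xp <- shift_pad(x4, shift, p)
  Np <- dim(xp)[1:3]
  nuc <- 0
  for (iz in seq_len(Np[3] / p)) for (iy in seq_len(Np[2] / p))
    for (ix in seq_len(Np[1] / p)) {
      xs <- ((ix - 1) * p + 1):(ix * p)
      ys <- ((iy - 1) * p + 1):(iy * p)
      zs <- ((iz - 1) * p + 1):(iz * p)
      M <- matrix(xp[xs, ys, zs, ], nrow = p^3, ncol = Tn)
      sv <- svd(M)
      if (is.null(tau)) {
        nuc <- nuc + sum(sv$d)
      } else {
        d <- pmax(sv$d - tau, 0)
        nuc <- nuc + sum(d)
        M2 <- sv$u %*% (d * Conj(t(sv$v)))
        xp[xs, ys, zs, ] <- array(M2, dim = c(p, p, p, Tn))
      }
    }
  if (is.null(tau)) return(nuc)
  list(x = unshift_crop(xp, shift, N), nuclear = nuc)
}

#' Locally-low-rank regularized reconstruction
#'
#' Minimizes `sum_f ||P F C x_f - y_f||^2 + lambda * sum_i ||R_i x||_*` by
#' accelerated proximal gradient (FISTA with a monotone safeguard): each
#' iteration takes a data-consistency gradient step followed by singular
#' value soft-thresholding of every space-by-time patch matrix (each
#' non-overlapping cubic patch unfolded to voxels x frames). A seeded
#' random cyclic shift of the patch tiling per iteration (cycle spinning)
#' suppresses blocking. The recorded objective is non-increasing; if an
#' accelerated step would increase it, the step is retaken without momentum
#' and the step size backtracked.
#'
#' @param prob a [recon_problem()] with at least 1 frame (2+ for a
#'   meaningful temporal rank structure).
#' @param config an [llr_config()].
#' @param x0 optional initial image series; default zero-filled.
#' @param verbose print per-iteration objectives.
#' @return complex 4D array with attributes `objective` (per-iteration
#'   data + regularization objective), `data_term`, `reg_term`,
#'   `iterations`.
#' @export
llr_recon <- function(prob, config = llr_config(), x0 = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(prob, "recon_problem"), inherits(config, "llr_config"))
  Tn <- prob$n_frames; N <- prob$N
  p <- config$patch

  # normalize so the unweighted adjoint image has unit peak magnitude
  adj0 <- array(0 + 0i, dim = c(N, Tn))
  for (f in seq_len(Tn)) adj0[, , , f] <- frame_adjoint(prob, f, prob$y[[f]])
  scale <- max(abs(adj0))
  if (scale <= 0) stop("all-zero data", call. = FALSE)
  yS <- lapply(prob$y, function(m) m / scale)

  # Lipschitz bound of the normal operator by power iteration
  set.seed(config$seed)
  v <- array(complex(real = rnorm(prod(N)), imaginary = rnorm(prod(N))),
             dim = N)
  v <- v / sqrt(sum(abs(v)^2))
  L <- 1
  for (it in 1:8) {
    fmax <- which.max(vapply(seq_len(Tn), function(f)
      prob$plans[[f]]$n_samples, numeric(1)))
    w <- frame_adjoint(prob, fmax, frame_forward(prob, fmax, v))
    L <- sqrt(sum(abs(w)^2))
    v <- w / max(L, 1e-300)
  }
  step <- 1 / (2 * L * 1.05)
  shifts <- matrix(sample.int(p, 3 * (config$max_iter + 1), replace = TRUE) - 1L,
                   ncol = 3)
  if (!config$cycle_spin)
    shifts <- matrix(shifts[1, ], config$max_iter + 1, 3, byrow = TRUE)

  grad_and_data <- function(x4) {
    g <- array(0 + 0i, dim = c(N, Tn)); dterm <- 0
    for (f in seq_len(Tn)) {
      r <- frame_forward(prob, f, x4[, , , f]) - yS[[f]]
      dterm <- dterm + sum(abs(r)^2)
      g[, , , f] <- 2 * frame_adjoint(prob, f, r)
    }
    list(g = g, data = dterm)
  }
  data_term_of <- function(x4) {
    d <- 0
    for (f in seq_len(Tn))
      d <- d + sum(abs(frame_forward(prob, f, x4[, , , f]) - yS[[f]])^2)
    d
  }
  objective_of <- function(x4, shift) {
    d <- data_term_of(x4)
    r <- if (config$lam > 0) config$lam * llr_patch_pass(x4, p, shift) else 0
    c(obj = d + r, data = d, reg = r)
  }
  prox <- function(x4, tau, shift) {
    if (config$lam == 0) return(list(x = x4, nuclear = 0))
    llr_patch_pass(x4, p, shift, tau = tau)
  }

  x <- if (is.null(x0)) array(0 + 0i, dim = c(N, Tn)) else (x0 / scale)
  z <- x; tk <- 1
  obj <- dat <- reg <- numeric(0)
  o_prev <- objective_of(x, shifts[1, ])
  for (it in seq_len(config$max_iter)) {
    sh <- shifts[it + 1, ]
    if (config$cycle_spin && it > 1) o_prev <- objective_of(x, sh)
    gd <- grad_and_data(z)
    cand <- prox(z - step * gd$g, step * config$lam, sh)
    o_new <- objective_of(cand$x, sh)
    if (o_new["obj"] > o_prev["obj"] + 1e-12 * abs(o_prev["obj"])) {
      # monotone safeguard: drop momentum, then backtrack the step
      for (bt in 1:10) {
        gd <- grad_and_data(x)
        cand <- prox(x - step * gd$g, step * config$lam, sh)
        o_new <- objective_of(cand$x, sh)
        if (o_new["obj"] <= o_prev["obj"] + 1e-12 * abs(o_prev["obj"]))
          break
        step <- step / 2
      }
      if (o_new["obj"] > o_prev["obj"] + 1e-10 * abs(o_prev["obj"]))
        stop("LLR solver failed to decrease the objective under backtracking",
             call. = FALSE)
      tk <- 1; z <- cand$x
    } else {
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- cand$x + ((tk - 1) / tk1) * (cand$x - x)
      tk <- tk1
    }
    relchg <- abs(o_prev["obj"] - o_new["obj"]) / max(abs(o_prev["obj"]), 1e-300)
    x <- cand$x
    obj <- c(obj, o_new["obj"]); dat <- c(dat, o_new["data"])
    reg <- c(reg, o_new["reg"])
    if (verbose)
      message(sprintf("iter %3d  obj %.6e  data %.3e  reg %.3e",
                      it, o_new["obj"], o_new["data"], o_new["reg"]))
    o_prev <- o_new
    if (relchg < config$tol) break
  }
  structure(x * scale, objective = unname(obj), data_term = unname(dat),
            reg_term = unname(reg), iterations = length(obj))
}

#' Control - label subtraction
#'
#' The labeled-blood (ASL) signal is the difference between control and
#' label acquisitions. By default the complex difference is taken before
#' the magnitude.
#'
#' @param control,label image arrays of identical shape.
#' @param mode `"complex"` (complex difference, then magnitude) or
#'   `"magnitude"` (difference of magnitudes).
#' @return real array of the ASL signal.
#' @export
subtract_label_control <- function(control, label,
                                   mode = c("complex", "magnitude")) {
  mode <- match.arg(mode)
  if (!identical(dim(control), dim(label)))
    stop_field("label", "shape must match `control`")
  if (mode == "complex") abs(control - label) else abs(control) - abs(label)
}

#' SVD coil compression
#'
#' Fits a linear compression on the data by singular value decomposition of
#' the coil-by-sample matrix and keeps the `n_out` dominant virtual coils.
#'
#' @param data complex C x S matrix (coils by samples; concatenate frames
#'   along columns to fit one compression for a whole acquisition).
#' @param n_out number of virtual coils to keep.
#' @return list with `data` (n_out x S), `mixing` (C x n_out, columns are
#'   the virtual-coil weights; apply as `Conj(t(mixing)) %*% x`), and
#'   `energy_fraction` retained.
#' @export
compress_coils <- function(data, n_out) {
  stopifnot(is.matrix(data))
  C <- nrow(data)
  if (n_out < 1 || n_out > C) stop_field("n_out", "must be in 1..n_coils")
  sv <- svd(data)
  U <- sv$u[, seq_len(n_out), drop = FALSE]
  list(data = Conj(t(U)) %*% data, mixing = U,
       energy_fraction = sum(sv$d[seq_len(n_out)]^2) / sum(sv$d^2))
}

#' Apply a coil compression to sensitivity maps
#'
#' @param coil_maps complex (nx, ny, nz, C) array.
#' @param mixing C x n_out mixing matrix from [compress_coils()].
#' @return compressed (nx, ny, nz, n_out) sensitivity array.
#' @export
compress_coil_maps <- function(coil_maps, mixing) {
  d <- dim(coil_maps)
  M <- matrix(coil_maps, ncol = d[4])
  out <- M %*% Conj(mixing)
  array(out, dim = c(d[1:3], ncol(mixing)))
}

#' Dual angiographic / perfusion reconstruction from one dataset
#'
#' From a single continuously acquired shot series, reconstructs (a) an
#' angiographic series using the full k-space extent at a short temporal
#' window (optionally only the first half of the repeats per window) and
#' (b) a perfusion series using only the central k-space region (radius
#' `perf_radius * k_max`) at a broader window on a proportionally coarser
#' grid.
#'
#' @param shot_data list over shots (0-based order matching the schedule)
#'   of complex C x S0 matrices of per-shot data.
#' @param schedule a [build_schedule()] result.
#' @param base_k one shot's base-frame samples (S0 x 3, 1/mm).
#' @param matrix,voxel_size image grid of the full-resolution
#'   reconstruction.
#' @param angio_window,perf_window temporal windows (ms).
#' @param perf_radius central k-space fraction for perfusion (default 1/3).
#' @param angio_half_shots use only the first half of repeats for
#'   angiography (default TRUE, mirroring the ~50x undersampled convention).
#' @param coil_maps optional sensitivity array for the full grid (perfusion
#'   maps are recomputed by nearest-grid subsampling when the grid is
#'   coarsened... supply `NULL` for uniform).
#' @param method `"adjoint"` or `"llr"`.
#' @param config an [llr_config()] for `method = "llr"`.
#' @param hann apply Hann apodization.
#' @return list with `angio` and `perfusion` complex 4D arrays and their
#'   `binning` objects.
#' @export
dual_reconstruct <- function(shot_data, schedule, base_k, matrix, voxel_size,
                             angio_window, perf_window, perf_radius = 1 / 3,
                             angio_half_shots = TRUE, coil_maps = NULL,
                             method = c("adjoint", "llr"),
                             config = llr_config(), hann = FALSE) {
  method <- match.arg(method)
  base_k <- as_kmat(base_k)
  one_branch <- function(window, radius, half, mat, vox, maps) {
    binning <- bin_frames(schedule, base_k, window,
                          k_radius_fraction = radius, half_shots = half)
    ks <- frame_samples(schedule, base_k, binning)
    keep <- binning$sample_keep
    plans <- lapply(ks, function(kk) nufft_plan(kk, mat, vox))
    y <- lapply(binning$frames, function(fr)
      do.call(cbind, lapply(fr$shots, function(s)
        shot_data[[s + 1]][, keep, drop = FALSE])))
    prob <- recon_problem(plans, y, coil_maps = maps)
    img <- if (method == "adjoint") adjoint_recon(prob, hann = hann)
           else llr_recon(prob, config)
    list(img = img, binning = binning)
  }
  a <- one_branch(angio_window, 1, angio_half_shots, matrix,
                  voxel_size, coil_maps)
  N <- as.integer(round(rep(matrix, length.out = 3)))
  Np <- pmax(2L, 2L * as.integer(ceiling(N * perf_radius / 2)))
  voxp <- rep(voxel_size, length.out = 3) * N / Np
  mapsp <- if (is.null(coil_maps)) NULL else {
    idx <- lapply(1:3, function(d) round(seq(1, N[d], length.out = Np[d])))
    coil_maps[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  p <- one_branch(perf_window, perf_radius, FALSE, Np, voxp, mapsp)
  list(angio = a$img, angio_binning = a$binning,
       perfusion = p$img, perfusion_binning = p$binning)
}
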