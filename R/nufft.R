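#' Non-uniform FFT plans (gridding with a Kaiser-Bessel kernel)
#'
#' A `nufft_plan` precomputes everything needed to evaluate the non-uniform
#' discrete Fourier transform of a 3D image at arbitrary k-space locations
#' (the "forward" or type-2 transform) and its exact adjoint (type-1,
#' gridding). The implementation is conventional: the image is deapodized,
#' zero-padded onto an oversampled grid, FFT'd, and interpolated at the
#' sample locations with a Kaiser-Bessel kernel; the adjoint reverses each
#' step, so `<F x, y> == <x, F' y>` holds to machine precision.
#'
#' Conventions: `k` is in 1/mm, `voxel_size` in mm, and the image origin is
#' the center voxel `floor(N/2)` (0-based), so a centered impulse transforms
#' to constant-magnitude data. Samples must satisfy `|k_d| <= 1/(2*voxel)`.
#'
#' @param k S x 3 matrix of k-space sample positions (1/mm).
#' @param matrix grid size, scalar or length-3 (voxels per dimension).
#' @param voxel_size voxel edge length in mm, scalar or length-3.
#' @param osf grid oversampling factor (default 2).
#' @param width Kaiser-Bessel kernel width in oversampled grid units
#'   (default 6; larger is more accurate and slower).
#' @return an object of class `nufft_plan`.
#' @export
nufft_plan <- function(k, matrix, voxel_size, osf = 2, width = 6) {
  k <- as_kmat(k)
  N <- as.integer(round(rep(matrix, length.out = 3)))
  vox <- rep(voxel_size, length.out = 3)
  if (any(N < 2)) stop_field("matrix", "grid must be at least 2 per dimension")
  if (any(vox <= 0)) stop_field("voxel_size", "must be positive")
  nu <- sweep(k, 2, vox, `*`)                    # cycles per voxel
  if (max(abs(nu)) > 0.5 + 1e-9)
    stop_field("k", "samples beyond the grid Nyquist frequency 1/(2*voxel)")
  Nos <- 2L * as.integer(ceiling(osf * N / 2))   # even oversampled dims
  u <- sweep(nu, 2, Nos, `*`)                    # grid frequency units, DC = 0
  beta <- pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
  deapod <- kb_deapod_array(N, Nos, width, beta)
  structure(list(k = k, N = N, Nos = Nos, vox = vox, u = u,
                 width = width, beta = beta, deapod = deapod,
                 n_samples = nrow(k)),
            class = "nufft_plan")
}

as_kmat <- function(k) {
  k <- as.matrix(k)
  if (ncol(k) != 3) stop_field("k", "must be an S x 3 matrix")
  storage.mode(k) <- "double"
  k
}

# Fourier transform of the (I0-normalized) Kaiser-Bessel kernel at
# frequency f cycles/grid-sample; sinh form inside the mainlobe.
kb_ft <- function(f, width, beta) {
  arg <- beta^2 - (pi * width * f)^2
  out <- numeric(length(arg))
  pos <- arg > 0
  out[pos] <- sinh(sqrt(arg[pos])) / sqrt(arg[pos])
  out[!pos] <- ifelse(arg[!pos] == 0, 1,
                      sin(sqrt(-arg[!pos])) / sqrt(-arg[!pos]))
  out * width / besselI(beta, 0)
}

kb_deapod_array <- function(N, Nos, width, beta) {
  cs <- lapply(1:3, function(d) {
    off <- (0:(N[d] - 1)) - floor(N[d] / 2)
    kb_ft(off / Nos[d], width, beta)
  })
  outer3(cs[[1]], cs[[2]], cs[[3]])
}

outer3 <- function(a, b, c) {
  ab <- outer(a, b)
  array(outer(ab, c), dim = c(length(a), length(b), length(c)))
}

circshift3 <- function(a, v) {
  d <- dim(a)
  idx <- lapply(1:3, function(i) ((seq_len(d[i]) - 1 - v[i]) %% d[i]) + 1L)
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Forward and adjoint NUFFT
#'
#' `nufft_forward` maps a 3D image to complex k-space samples
#' \eqn{y_s = \sum_j x_j e^{-2\pi i k_s \cdot r_j}} (with \eqn{r_j} the voxel
#' position relative to the center voxel, in mm); `nufft_adjoint` is its exact
#' adjoint, gridding samples back to an image.
#'
#' @param plan a [nufft_plan()].
#' @param x 3D (possibly complex) image array matching the plan's grid.
#' @param y complex vector of samples, one per plan sample.
#' @return `nufft_forward`: complex vector of length `plan$n_samples`;
#'   `nufft_adjoint`: complex 3D array on the plan grid.
#' @export
nufft_forward <- function(plan, x) {
  stopifnot(inherits(plan, "nufft_plan"))
  x <- as.array(x)
  if (!identical(dim(x), as.integer(plan$N)))
    stop_field("x", "image dimensions do not match the plan grid")
  N <- plan$N; Nos <- plan$Nos
  xi <- x / plan$deapod
  pad <- array(0 + 0i, dim = Nos)
  lo <- floor(Nos / 2) - floor(N / 2) + 1L
  pad[lo[1]:(lo[1] + N[1] - 1), lo[2]:(lo[2] + N[2] - 1),
      lo[3]:(lo[3] + N[3] - 1)] <- xi
  pad <- circshift3(pad, -floor(Nos / 2))
  G <- fft(pad)
  kb_interp3(as.complex(G), as.integer(Nos), plan$u, plan$width, plan$beta)
}

#' @rdname nufft_forward
#' @export
nufft_adjoint <- function(plan, y) {
  stopifnot(inherits(plan, "nufft_plan"))
  y <- as.complex(y)
  if (length(y) != plan$n_samples)
    stop_field("y", "sample count does not match the plan")
  N <- plan$N; Nos <- plan$Nos
  H <- kb_spread3(plan$u, y, as.integer(Nos), plan$width, plan$beta)
  H <- array(H, dim = Nos)
  h <- fft(H, inverse = TRUE)
  h <- circshift3(h, floor(Nos / 2))
  lo <- floor(Nos / 2) - floor(N / 2) + 1L
  h <- h[lo[1]:(lo[1] + N[1] - 1), lo[2]:(lo[2] + N[2] - 1),
         lo[3]:(lo[3] + N[3] - 1)]
  h / plan$deapod
}

#' Direct (slow) non-uniform DFT, for validation at small sizes
#'
#' Evaluates the same transform as [nufft_forward()] by explicit summation.
#' O(S * Nvox); intended as an independent reference on small grids.
#'
#' @inheritParams nufft_plan
#' @param x 3D image array.
#' @param adjoint if `TRUE`, computes the adjoint of samples `x` (a complex
#'   vector of length S) instead, returning a 3D array.
#' @return complex samples (forward) or a complex 3D array (adjoint).
#' @export
nufft_direct <- function(x, k, matrix, voxel_size, adjoint = FALSE) {
  k <- as_kmat(k)
  N <- as.integer(round(rep(matrix, length.out = 3)))
  vox <- rep(voxel_size, length.out = 3)
  coords <- as.matrix(expand.grid(
    x = ((0:(N[1] - 1)) - floor(N[1] / 2)) * vox[1],
    y = ((0:(N[2] - 1)) - floor(N[2] / 2)) * vox[2],
    z = ((0:(N[3] - 1)) - floor(N[3] / 2)) * vox[3]))
  phase <- k %*% t(coords)                       # S x Nvox, cycles
  if (!adjoint) {
    E <- exp(-2i * pi * phase)
    as.vector(E %*% as.complex(as.vector(x)))
  } else {
    E <- exp(2i * pi * phase)
    array(as.vector(t(E) %*% as.complex(x)), dim = N)
  }
}
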