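# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they stand in judgment of one.

# straight radial spokes along given unit axes at given radii -- an
# independent construction of a 3D golden-ratio radial sample set
radial_samples <- function(axes, radii) {
  do.call(rbind, lapply(seq_len(nrow(axes)), function(i) outer(radii, axes[i, ])))
}

# Monte-Carlo spherical-cap discrepancy: max over random caps of
# |empirical fraction - cap area fraction|
cap_discrepancy <- function(axes, n_caps = 200, seed = 99) {
  set.seed(seed)
  n <- nrow(axes)
  z <- runif(n_caps, -1, 1)
  az <- runif(n_caps, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  centers <- cbind(r * cos(az), r * sin(az), z)
  cosang <- runif(n_caps, -1, 1)            # random cap sizes
  emp <- vapply(seq_len(n_caps), function(j)
    mean(axes %*% centers[j, ] >= cosang[j]), numeric(1))
  area <- (1 - cosang) / 2
  max(abs(emp - area))
}

# uniformly random unit vectors
random_axes <- function(n, seed) {
  set.seed(seed)
  z <- runif(n, -1, 1)
  az <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(az), r * sin(az), z)
}

# conjugate-gradient solve of the normal equations A'A x = A'y for a
# recon_problem -- the least-squares oracle for llr_recon at lambda = 0
cg_solve <- function(prob, max_iter = 80, tol = 1e-12) {
  Tn <- prob$n_frames; N <- prob$N
  AtA <- function(v4) {
    out <- array(0 + 0i, dim = c(N, Tn))
    for (f in seq_len(Tn))
      out[, , , f] <- conetraj:::frame_adjoint(
        prob, f, conetraj:::frame_forward(prob, f, v4[, , , f]))
    out
  }
  b <- array(0 + 0i, dim = c(N, Tn))
  for (f in seq_len(Tn))
    b[, , , f] <- conetraj:::frame_adjoint(prob, f, prob$y[[f]])
  x <- array(0 + 0i, dim = c(N, Tn))
  r <- b; p <- r; rs <- sum(abs(r)^2)
  for (i in seq_len(max_iter)) {
    Ap <- AtA(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(abs(r)^2)
    if (sqrt(rs2) < tol) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  x
}

# full Cartesian grid sample positions for an N^3 image at voxel size vox
cartesian_samples <- function(N, vox) {
  f <- ((0:(N - 1)) - N %/% 2) / (N * vox)
  as.matrix(expand.grid(x = f, y = f, z = f))
}

rel_rms <- function(a, b) sqrt(mean(abs(a - b)^2)) / sqrt(mean(abs(b)^2))
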