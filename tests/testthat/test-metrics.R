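test_that("density compensation: uniform on a grid, halves on duplication", {
  N <- 12
  k <- cartesian_samples(N, 1)
  w <- density_compensation(k, N, 1)
  expect_lt((max(w) - min(w)) / mean(w), 0.01)
  wd <- density_compensation(rbind(k, k), N, 1)
  expect_lt(max(abs(wd[seq_len(nrow(k))] / w - 0.5)), 0.01)
  expect_error(density_compensation(matrix(numeric(0), 0, 3), 8, 1), "sample")
  expect_length(attr(w, "convergence"), 20)
})

test_that("density weights follow the analytic quadratic law for dense radial", {
  ax <- golden_axis(0:1599)
  rr <- seq(0.01, 0.5, length.out = 48)
  ks <- radial_samples(ax, rr)
  w <- density_compensation(ks, 16, 1)
  r <- sqrt(rowSums(ks^2))
  # interior shell: the analytic density of dense radial sampling is 1/r^2,
  # so the mean weight per radius grows as r^2 (the outermost shell is a
  # truncation boundary and is excluded)
  mw <- tapply(w, round(r, 6), mean)
  mr <- as.numeric(names(mw))
  sel <- mr > 0.1 * 0.5 & mr < 0.7 * 0.5
  fit <- stats::lm(mw[sel] ~ I(mr[sel]^2))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("PSF of full Cartesian sampling is a unit delta; Hann broadens it", {
  N <- 16
  k <- cartesian_samples(N, 1)
  plan <- nufft_plan(k, N, 1, width = 8)
  p <- psf(plan, weights = rep(1, nrow(k)))
  pk <- which.max(p)
  expect_equal(arrayInd(pk, dim(p))[1, ], rep(N / 2 + 1, 3), ignore_attr = TRUE)
  off <- p; off[pk] <- 0
  expect_lt(max(off), 1e-6)
  # Hann apodization never decreases the FWHM
  ax <- golden_axis(0:799)
  ks <- radial_samples(ax, seq(0.02, 0.5, length.out = 32))
  plan2 <- nufft_plan(ks, 24, 1)
  w2 <- density_compensation(plan2)
  f_plain <- fwhm(psf(plan2, weights = w2), 1)
  f_hann <- fwhm(psf(plan2, weights = w2, hann = TRUE), 1)
  expect_true(all(f_hann$mm >= f_plain$mm - 1e-6))
})

test_that("1D cut through a finely gridded Cartesian PSF matches the Dirichlet kernel", {
  # N^3 Cartesian samples reconstructed on a 3x finer grid: the x profile
  # is the periodic sinc D(u) = sin(pi N u dk x) / (N sin(pi u))
  N <- 8; M <- 24; vox <- 1
  k <- cartesian_samples(N, vox)
  plan <- nufft_plan(k, M, vox / 3, width = 8)
  p <- psf(plan, weights = rep(1, nrow(k)))
  prof <- p[, M / 2 + 1, M / 2 + 1]
  xs <- ((0:(M - 1)) - M / 2) * (vox / 3)
  u <- xs / (N * vox)                       # cycles per sample spacing
  expected <- abs(vapply(u, function(ui) {
    if (abs(sin(pi * ui)) < 1e-14) 1 else
      sin(pi * N * ui) / (N * sin(pi * ui))
  }, numeric(1)))
  expect_lt(max(abs(prof - expected)), 1e-6)
})

test_that("FWHM recovers the Gaussian closed form and Fourier scaling", {
  N <- 48; sig <- 2.2
  axn <- (1:N) - (N / 2 + 1)
  g <- exp(-outer(outer(axn^2, axn^2, `+`), axn^2, `+`) / (2 * sig^2))
  fw <- fwhm(g, voxel_size = 1)
  expect_equal(fw$voxels, rep(2.3548 * sig, 3), tolerance = 0.01)
  # isotropic profile: three widths agree
  expect_lt(diff(range(fw$voxels)), 1e-6)
  # doubling k_max at fixed geometry halves the FWHM in mm; analytic r^2
  # weights isolate pure Fourier scaling from density-estimation effects,
  # and both widths stay well above the voxel lattice
  ax <- golden_axis(0:599)
  rr <- seq(0.005, 0.125, length.out = 24)
  k1 <- radial_samples(ax, rr); k2 <- radial_samples(ax, 2 * rr)
  f1 <- fwhm(psf(k1, weights = rowSums(k1^2), matrix = 48, voxel_size = 1), 1)
  f2 <- fwhm(psf(k2, weights = rowSums(k2^2), matrix = 48, voxel_size = 1), 1)
  expect_equal(f2$mm, f1$mm / 2, tolerance = 0.02)
  # non-decaying profile has no measurable width
  expect_error(fwhm(array(1, c(8, 8, 8)), 1), "boundary|decay")
})

test_that("SAPR matches hand arithmetic and its invariances", {
  img <- array(0, c(4, 4, 4))
  fg <- bg <- array(FALSE, c(4, 4, 4))
  img[1] <- 2; fg[1] <- TRUE
  img[2] <- 1; bg[2] <- TRUE
  expect_equal(sapr(img, fg, bg), 4)
  expect_equal(sapr(10 * img, fg, bg), 4)      # scale invariance
  img[2] <- 0
  r <- sapr(img, fg, bg)
  expect_true(is.infinite(r))
  expect_true(attr(r, "zero_background"))
  fg2 <- fg; fg2[2] <- TRUE
  expect_error(sapr(img, fg2, bg), "disjoint")
})

test_that("pseudo-replica noise scaling, determinism, and propagation", {
  set.seed(4)
  ax <- golden_axis(0:299)
  ks <- radial_samples(ax, seq(0.02, 0.5, length.out = 24))
  N <- 24
  plan <- nufft_plan(ks, N, 1)
  w <- density_compensation(plan)
  ph <- make_vessel_phantom(32, 1, seed = 2)
  vol <- ph$volume[1:N, 1:N, 1:N]
  fg <- vol != 0
  y <- simulate_acquisition(vol, NULL, plan)
  e1 <- effective_snr(y, plan, w, fg, 0.02, n_replicas = 48, seed = 5)
  e2 <- effective_snr(y, plan, w, fg, 0.04, n_replicas = 48, seed = 5)
  expect_equal(e1$eff_snr / e2$eff_snr, 2, tolerance = 0.08)
  # determinism under the seed
  e1b <- effective_snr(y, plan, w, fg, 0.02, n_replicas = 48, seed = 5)
  expect_identical(e1$eff_snr, e1b$eff_snr)
  # linear propagation oracle: complex std of the weighted adjoint of pure
  # noise equals sigma * sqrt(2 * sum(w^2)) per voxel
  sig <- 0.3
  set.seed(11)
  reps <- vapply(1:96, function(r) {
    nn <- complex(real = rnorm(nrow(ks), sd = sig),
                  imaginary = rnorm(nrow(ks), sd = sig))
    img <- nufft_adjoint(plan, nn * w)
    c(Re(img[13, 13, 13]), Im(img[13, 13, 13]))
  }, numeric(2))
  emp <- sqrt(sd(reps[1, ])^2 + sd(reps[2, ])^2)
  expect_equal(emp, sig * sqrt(2 * sum(w^2)), tolerance = 0.3)
  expect_error(effective_snr(y, plan, w, array(FALSE, dim(fg)), 0.02),
               "foreground")
})

test_that("metrics are invariant to rigid rotation of the trajectory", {
  ax <- golden_axis(0:399)
  ks <- radial_samples(ax, seq(0.02, 0.45, length.out = 24))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  f1 <- fwhm(psf(ks, matrix = 24, voxel_size = 1), 1)
  f2 <- fwhm(psf(ks %*% t(R), matrix = 24, voxel_size = 1), 1)
  expect_equal(mean(f2$mm), mean(f1$mm), tolerance = 0.02)
})
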