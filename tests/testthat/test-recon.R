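make_small_problem <- function(N = 16, Tn = 3, n_coils = 2, seed = 21,
                               scale = 1) {
  set.seed(seed)
  k <- cartesian_samples(N, 1)
  coils <- make_coil_model(N, n_coils)
  maps <- coils$sensitivities * scale
  plans <- lapply(seq_len(Tn), function(f) nufft_plan(k, N, 1))
  ph <- make_vessel_phantom(32, 1, seed = seed)$volume[1:N, 1:N, 1:N]
  y <- lapply(seq_len(Tn), function(f)
    simulate_acquisition(ph * (0.6 + 0.4 * f / Tn), coils, plans[[f]]) * scale)
  recon_problem(plans, y, coil_maps = maps)
}

test_that("adjoint recon recovers a fully sampled single-coil phantom", {
  N <- 16
  k <- cartesian_samples(N, 1)
  plan <- nufft_plan(k, N, 1)
  ph <- make_vessel_phantom(32, 1, seed = 3)$volume[1:N, 1:N, 1:N]
  y <- simulate_acquisition(ph, NULL, plan)
  prob <- recon_problem(list(plan), list(y))
  img <- adjoint_recon(prob, weights = list(rep(1 / N^3, nrow(k))))
  expect_lt(rel_rms(img[, , , 1], ph), 1e-3)
  # output is linear in the data
  y2 <- y * (1 + 0.5i)
  img2 <- adjoint_recon(recon_problem(list(plan), list(y2)),
                        weights = list(rep(1 / N^3, nrow(k))))
  expect_lt(max(abs(img2 - img * (1 + 0.5i))) / max(abs(img2)), 1e-10)
})

test_that("uniform coil maps reduce coil combination to a plain average", {
  N <- 12
  k <- cartesian_samples(N, 1)
  plan <- nufft_plan(k, N, 1)
  ph <- array(rnorm(N^3), dim = c(N, N, N))
  y1 <- nufft_forward(plan, ph)
  y <- rbind(y1, y1)
  maps <- array(1 + 0i, dim = c(N, N, N, 2))
  w <- list(rep(1 / N^3, nrow(k)))
  with_maps <- adjoint_recon(recon_problem(list(plan), list(y), maps), w)
  no_maps <- adjoint_recon(recon_problem(list(plan), list(y)), w)
  expect_lt(max(abs(with_maps - no_maps)), 1e-10)
})

test_that("LLR at lambda = 0 matches the conjugate-gradient least-squares oracle", {
  prob <- make_small_problem(N = 16, Tn = 3)
  x <- llr_recon(prob, llr_config(lam = 0, max_iter = 120, tol = 1e-11))
  xc <- cg_solve(prob, max_iter = 60)
  expect_lt(rel_rms(x, xc), 1e-3)
  obj <- attr(x, "objective")
  expect_true(all(diff(obj) <= 1e-9 * pmax(abs(obj[-length(obj)]), 1e-300)))
})

test_that("LLR structural properties: rank-1 symmetry, threshold dominance, gauge", {
  prob <- make_small_problem(N = 16, Tn = 3)
  # identical data in every frame: frames of the solution agree
  y_same <- lapply(seq_len(3), function(f) prob$y[[1]])
  prob_same <- recon_problem(prob$plans, y_same, prob$coil_maps)
  xs <- llr_recon(prob_same, llr_config(lam = 0.05, max_iter = 25))
  expect_lt(max(abs(xs[, , , 1] - xs[, , , 3])) / max(abs(xs)), 1e-4)
  obj <- attr(xs, "objective")
  expect_true(all(diff(obj) <= 1e-9 * pmax(abs(obj[-length(obj)]), 1e-300)))
  # overwhelming regularization drives the solution to zero
  x0 <- llr_recon(prob, llr_config(lam = 1e6, max_iter = 5))
  expect_lt(max(abs(x0)), 1e-8 * max(abs(adjoint_recon(prob))))
  # consistent rescaling of y and C leaves the lambda = 0 solution invariant
  prob_scaled <- make_small_problem(N = 16, Tn = 3, scale = 3)
  xa <- llr_recon(prob, llr_config(lam = 0, max_iter = 60, tol = 1e-10))
  xb <- llr_recon(prob_scaled, llr_config(lam = 0, max_iter = 60, tol = 1e-10))
  expect_lt(rel_rms(xb, xa), 1e-3)
})

test_that("control - label subtraction isolates the difference signal", {
  a <- array(complex(real = rnorm(64), imaginary = rnorm(64)), dim = c(4, 4, 4))
  expect_true(all(subtract_label_control(a, a) == 0))
  mask <- array(FALSE, c(4, 4, 4)); mask[c(3, 17, 40)] <- TRUE
  b <- a; b[mask] <- b[mask] - 0.2
  d <- subtract_label_control(a, b)
  expect_true(all(d[mask] > 0))
  expect_true(all(d[!mask] == 0))
  # linear in both arguments (complex difference mode)
  d2 <- subtract_label_control(2 * a, 2 * b)
  expect_equal(d2, 2 * d, tolerance = 1e-12)
  expect_error(subtract_label_control(a, a[1:2, , ]), "shape")
})

test_that("coil compression retains energy and commutes with reconstruction", {
  prob <- make_small_problem(N = 12, Tn = 1, n_coils = 4)
  dat <- prob$y[[1]]
  # keeping all coils keeps all energy
  cc_full <- compress_coils(dat, 4)
  expect_equal(cc_full$energy_fraction, 1, tolerance = 1e-12)
  # constructed rank-2 coil data compresses to 2 channels losslessly
  low <- rbind(dat[1, ] + dat[2, ], 2 * dat[1, ] - dat[2, ],
               0.5 * dat[1, ], dat[2, ])
  cc2 <- compress_coils(low, 2)
  expect_gt(cc2$energy_fraction, 0.999)
  # unitary (full-rank) compression leaves the combined recon unchanged
  maps_c <- compress_coil_maps(prob$coil_maps, cc_full$mixing)
  w <- list(rep(1, ncol(dat)))
  img_orig <- adjoint_recon(prob, w)
  img_comp <- adjoint_recon(recon_problem(prob$plans,
                                          list(cc_full$data), maps_c), w)
  expect_lt(max(abs(img_orig - img_comp)) / max(abs(img_orig)), 1e-6)
  expect_error(compress_coils(dat, 9), "n_out")
})

test_that("dual reconstruction: identity configuration and frame counts", {
  lim <- hardware_limits()
  res <- 2
  p <- cone_params(50, 0.5, 3, A = 8, k_max = kmax_for_resolution(res),
                   readout_duration = 3)
  w <- time_optimal_waveform(base_cone(p, 2500), lim)
  adc <- resample_adc(w, 10)
  pr <- protocol_params(12, 96)
  sch <- build_schedule(pr, 4, seed = 2)
  N <- 24
  ph <- make_vessel_phantom(32, res, seed = 1)$volume[1:N, 1:N, 1:N]
  shot_data <- lapply(seq_len(nrow(sch$shots)), function(s) {
    kk <- rotate_samples(sch, adc$k, shots = sch$shots$shot[s])
    simulate_acquisition(ph, NULL, kk, voxel_size = res)
  })
  dr <- dual_reconstruct(shot_data, sch, adc$k, N, res,
                         angio_window = 48, perf_window = 96,
                         perf_radius = 1 / 3, method = "adjoint")
  expect_equal(dim(dr$angio)[4], 2L)
  expect_equal(dim(dr$perfusion)[4], 1L)
  # perfusion grid is proportionally coarser
  expect_lt(dim(dr$perfusion)[1], N / 2)
  # identity configuration: both branches coincide
  dr2 <- dual_reconstruct(shot_data, sch, adc$k, N, res,
                          angio_window = 96, perf_window = 96,
                          perf_radius = 1, angio_half_shots = FALSE,
                          method = "adjoint")
  expect_equal(dr2$angio, dr2$perfusion, tolerance = 1e-12)
})
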