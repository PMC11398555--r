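test_that("required gradient inverts the b-value relation", {
  pr <- pgse_protocol()
  g <- required_gradient(pr)
  b_back <- pr$gamma^2 * g^2 * pr$delta_ms^2 * (pr$Delta_ms - pr$delta_ms / 3)
  expect_equal(b_back * 1e3, 500, tolerance = 1e-10)
  expect_equal(required_gradient(pgse_protocol(b_s_per_mm2 = 0)), 0)
  # doubling delta at fixed b and (Delta - delta/3) halves g
  pr2 <- pgse_protocol(delta_ms = 6.2, Delta_ms = pr$Delta_ms - pr$delta_ms / 3 + 6.2 / 3)
  expect_equal(required_gradient(pr2), g / 2, tolerance = 1e-12)
})

test_that("protocol validation refuses bad geometry and directions", {
  expect_error(pgse_protocol(delta_ms = 20, Delta_ms = 15), "delta")
  expect_error(pgse_protocol(directions = matrix(c(1, 1, 0), 1)), "unit")
  expect_error(pgse_protocol(b_s_per_mm2 = -5))
})

test_that("free diffusion: per-axis MSD grows as 2 D t", {
  lab <- as_fiber_label_map(matrix(1L, 40, 40), 2)
  sub <- substrate_geometry(lab, D_intra = 2, D_extra = 2, kappa = 0)
  n <- 15000; t_tot <- 18
  w <- simulate_walkers(sub, n, 0.05, t_tot, seed = 3, save_every = 0)
  start3 <- cbind(w$start, 0)                    # z starts at 0
  for (ax in 1:3) {
    v <- var(w$final[, ax] - start3[, ax])
    se <- 2 * 2 * t_tot * sqrt(2 / (n - 1))
    expect_lt(abs(v - 2 * 2 * t_tot), 3 * se)
  }
  expect_equal(w$n_steps * 0.05, t_tot)
})

test_that("free diffusion PGSE signal matches exp(-bD)", {
  lab <- as_fiber_label_map(matrix(1L, 40, 40), 2)
  sub <- substrate_geometry(lab, D_intra = 2, D_extra = 2, kappa = 0)
  pr <- pgse_protocol()
  n <- 20000
  w <- simulate_walkers(sub, n, 0.05, pr$Delta_ms + pr$delta_ms, seed = 3)
  sig <- pgse_signal(w, pr, c(1, 0, 0))
  truth <- exp(-0.5 * 2)                        # b = 0.5 ms/um2, D = 2 um2/ms
  se <- sqrt((1 - truth^2) / (2 * n))
  expect_lt(abs(sig - truth), 3 * se)
  expect_equal(pgse_signal(w, pgse_protocol(b_s_per_mm2 = 0), c(1, 0, 0)), 1)
})

test_that("impermeable membranes: no crossings, saturating displacement variance", {
  d <- disc_label_map(4, 0.1, margin_um = 2)
  sub <- substrate_geometry(d, D_intra = 1, D_extra = 1, kappa = 0, wrap = FALSE)
  n <- 8000
  set.seed(4)
  W <- ncol(d$labels) * d$pixel_size_um
  pts <- cbind(runif(8 * n, 0, W), runif(8 * n, 0, W))
  ctr <- W / 2
  pts <- pts[(pts[, 1] - ctr)^2 + (pts[, 2] - ctr)^2 <= 4^2, ][seq_len(n), ]
  w <- simulate_walkers(sub, n, 0.02, 80, seed = 5, start = pts, save_every = 0)
  expect_equal(w$crossings, 0)
  # long-time variance of x(t) - x(0): two independent uniform points in the
  # disc give a^2/2 per axis
  v <- var(w$final[, 1] - pts[, 1])
  expect_lt(abs(v - 4^2 / 2) / (4^2 / 2), 0.05)
  # walker conservation
  expect_equal(nrow(w$final), n)
})

test_that("axial diffusion along the fiber axis stays free under restriction", {
  m <- small_packing(seed = 31)
  sub <- substrate_geometry(m, D_intra = 1.2, D_extra = 1.2, kappa = 0)
  pr <- pgse_protocol()
  n <- 15000
  w <- simulate_walkers(sub, n, 0.1, pr$Delta_ms + pr$delta_ms, seed = 8)
  sig_ax <- pgse_signal(w, pr, c(0, 0, 1))
  truth <- exp(-0.5 * 1.2)
  se <- sqrt((1 - truth^2) / (2 * n))
  expect_lt(abs(sig_ax - truth), 3 * se)
})

test_that("time step preconditions are enforced with a suggested dt", {
  m <- small_packing(seed = 31)
  sub <- substrate_geometry(m, D_intra = 2, D_extra = 2, kappa = 0)
  expect_error(simulate_walkers(sub, 10, dt_ms = 5, duration_ms = 10),
               "dt_ms <=")
})

test_that("membrane transmission reproduces kappa-limited exchange flux", {
  # two L = 20 um slabs exchanging through a membrane of permeability kappa.
  # Exact oracle: the slowest relaxation mode of the two-slab problem,
  # tau = 1 / (D q^2) with tan(q L) = 2 kappa / (D q) (reflecting outer
  # walls); in the membrane-limited limit this reduces to L / (2 kappa).
  L <- 20; D <- 2; kappa <- 0.01
  q <- uniroot(function(q) tan(q * L) - 2 * kappa / (D * q),
               c(1e-5, pi / (2 * L) * 0.999), tol = 1e-12)$root
  tau_theory <- 1 / (D * q^2)
  lab <- cbind(matrix(1L, 60, 100), matrix(2L, 60, 100))
  sub <- substrate_geometry(as_fiber_label_map(lab, 0.2), D_intra = D,
                            D_extra = D, kappa = kappa, wrap = FALSE)
  n <- 6000
  set.seed(7)
  start <- cbind(runif(n, 0, L), runif(n, 0, 12))
  w <- simulate_walkers(sub, n, 0.03, 750, seed = 6, start = start,
                        save_every = 2500)
  frac_left <- apply(w$traj[1, , ], 2, function(x) mean(x < L))
  tt <- (seq_along(frac_left) - 1) * 2500 * 0.03
  tau <- -1 / coef(lm(log(frac_left - 0.5) ~ tt))[[2]]
  expect_lt(abs(tau - tau_theory) / tau_theory, 0.05)
  expect_gt(w$crossings, 0)
})

test_that("synthesized DWI volumes have exact b0, Rician background, SNR-consistent spread", {
  lab <- as_fiber_label_map(matrix(1L, 1500, 1500), 1)   # homogeneous 1.5 mm
  pr <- pgse_protocol()
  noiseless <- synthesize_dwi(lab, list(kappa = 0), pr, voxel_size_mm = 0.5,
                              snr_b0 = Inf, seed = 2, n_walkers_per_voxel = 400,
                              n_background = 0)
  expect_true(all(noiseless$signals[, , 1:5] == 1))
  expect_true(all(noiseless$signals >= 0))
  expect_equal(dim(noiseless$signals), c(3, 3, 35))

  snr <- 40
  noisy <- synthesize_dwi(lab, list(kappa = 0), pr, voxel_size_mm = 0.5,
                          snr_b0 = snr, seed = 2, n_walkers_per_voxel = 400,
                          n_background = 300)
  # noise-only voxels follow a Rayleigh law: mean sigma sqrt(pi/2)
  bg <- as.vector(noisy$background)
  sigma <- 1 / snr
  expect_lt(abs(mean(bg) - sigma * sqrt(pi / 2)),
            3 * sigma * sqrt((2 - pi / 2) / length(bg)))
  # b0 voxel spread consistent with 1/snr
  b0 <- as.vector(noisy$signals[, , 1:5])
  expect_lt(abs(sd(b0) - sigma) / sigma, 3 / sqrt(2 * (length(b0) - 1)) + 0.1)
})

test_that("a voxel grid larger than the substrate is refused", {
  lab <- as_fiber_label_map(matrix(1L, 100, 100), 1)     # 0.1 mm section
  expect_error(synthesize_dwi(lab, voxel_size_mm = 0.5), "larger than")
})

test_that("DWI volumes round-trip through NIfTI + bval/bvec", {
  lab <- as_fiber_label_map(matrix(1L, 600, 600), 1)
  dwi <- synthesize_dwi(lab, list(kappa = 0), pgse_protocol(directions = 8),
                        voxel_size_mm = 0.5, snr_b0 = 50, seed = 3,
                        n_walkers_per_voxel = 100, n_background = 0)
  stem <- file.path(tempdir(), "dwi")
  write_dwi(dwi, stem)
  back <- read_dwi(stem)
  expect_equal(back$signals, dwi$signals, tolerance = 1e-6)
  expect_equal(back$bvals, dwi$bvals)
  expect_equal(back$bvecs, dwi$bvecs, tolerance = 1e-6)
  expect_equal(back$voxel_size_mm, 0.5)
})

test_that("restriction grows with diffusion time for impermeable fibers", {
  m <- small_packing(seed = 37, mean_d = 24, cv = 0.15)
  sp <- list(D_intra = 1.0, D_extra = 1.0, kappa = 0)
  fit_at <- function(Delta) {
    pr <- pgse_protocol(Delta_ms = Delta, directions = 12)
    dwi <- synthesize_dwi(m, sp, pr, voxel_size_mm = 0.35, snr_b0 = Inf,
                          seed = 11, n_walkers_per_voxel = 3000, dt_ms = 0.05,
                          n_background = 0)
    tf <- fit_tensor_field(dwi)
    c(fa = mean(tf$fa), rd = mean(tf$rd))
  }
  short <- fit_at(8)
  long <- fit_at(40)
  expect_gt(long[["fa"]], short[["fa"]])
  expect_lt(long[["rd"]], short[["rd"]])
})
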