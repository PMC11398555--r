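test_that("noiseless tensor fits are exact to solver tolerance", {
  pr <- pgse_protocol()
  sig <- signals_for_tensor(diag(c(1.6, 1.2, 1.2) * 1e-3), pr)
  ft <- fit_tensor(sig$signals, sig$bvals, sig$bvecs)
  expect_equal(ft$eigenvalues, c(1.6, 1.2, 1.2) * 1e-3, tolerance = 1e-8)
  expect_false(ft$clamped_flag)
  # isotropic: FA numerically zero
  iso <- signals_for_tensor(diag(rep(1e-3, 3)), pr)
  expect_lt(fit_tensor(iso$signals, iso$bvals, iso$bvecs)$fa, 1e-8)
})

test_that("noiseless round trip is exact for random SPD tensors and is rotation-equivariant", {
  pr <- pgse_protocol()
  set.seed(42)
  for (k in 1:20) {
    D <- random_spd_tensor()
    sig <- signals_for_tensor(D, pr)
    ft <- fit_tensor(sig$signals, sig$bvals, sig$bvecs)
    expect_equal(ft$tensor, D, tolerance = 1e-8)
  }
  # rotating bvecs and the truth together leaves the scalar maps unchanged
  D <- diag(c(1.8, 0.9, 0.6) * 1e-3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  pr_rot <- pr; pr_rot$directions <- pr$directions %*% t(Q)
  sig <- signals_for_tensor(D, pr)
  sig_rot <- signals_for_tensor(Q %*% D %*% t(Q), pr_rot)
  f1 <- fit_tensor(sig$signals, sig$bvals, sig$bvecs)
  sig_rot_b <- rbind(matrix(0, pr$n_b0, 3), pr_rot$directions)
  f2 <- fit_tensor(sig_rot$signals, sig_rot$bvals, sig_rot$bvecs)
  expect_equal(c(f1$fa, f1$md, f1$rd), c(f2$fa, f2$md, f2$rd), tolerance = 1e-10)
})

test_that("fit agrees with an independent OLS pseudoinverse implementation", {
  pr <- pgse_protocol()
  bvals <- c(rep(0, pr$n_b0), rep(pr$b_s_per_mm2, 30))
  bvecs <- rbind(matrix(0, pr$n_b0, 3), pr$directions)
  # independent route: plain pseudoinverse on log-signals, no weighting,
  # no b0 averaging
  g <- bvecs
  X <- cbind(1, -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
             -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
             -2 * bvals * g[, 2] * g[, 3])
  Xp <- solve(t(X) %*% X, t(X))
  set.seed(7)
  worst <- 0
  for (k in 1:100) {
    D <- random_spd_tensor()
    s <- exp(-bvals * rowSums((bvecs %*% D) * bvecs))
    th <- Xp %*% log(s)
    ev_ref <- sort(eigen(matrix(c(th[2], th[5], th[6], th[5], th[3], th[7],
                                  th[6], th[7], th[4]), 3, 3),
                         symmetric = TRUE, only.values = TRUE)$values,
                   decreasing = TRUE)
    ev_fit <- fit_tensor(s, bvals, bvecs)$eigenvalues
    worst <- max(worst, max(abs(ev_fit - ev_ref) / ev_ref))
  }
  expect_lt(worst, 1e-6)
})

test_that("degenerate voxels are masked or clamped with flags", {
  pr <- pgse_protocol()
  sig <- signals_for_tensor(diag(c(1.6, 1.2, 1.2) * 1e-3), pr)
  s_bad <- sig$signals; s_bad[10] <- 0
  ft <- fit_tensor(s_bad, sig$bvals, sig$bvecs)
  expect_false(ft$ok)
  expect_match(ft$reason, "non-positive")
  # rank-deficient design: all directions along x
  bvecs_bad <- rbind(matrix(0, 1, 3), matrix(rep(c(1, 0, 0), 8), 8, 3, byrow = TRUE))
  expect_error(fit_tensor(exp(-c(0, rep(0.5, 8))), c(0, rep(500, 8)), bvecs_bad),
               "rank-deficient")
})

test_that("tensor scalar formulas match hand-evaluated cases", {
  iso <- tensor_scalars(c(1, 1, 1) * 1e-3)
  expect_equal(iso$fa, 0)
  expect_equal(iso$md, 1e-3)
  expect_equal(iso$rd, 1e-3)
  stick <- tensor_scalars(c(2, 0, 0) * 1e-3)
  expect_equal(stick$fa, 1)
  musc <- tensor_scalars(c(1.6, 1.2, 1.2) * 1e-3)
  expect_equal(musc$md, 1.3333e-3, tolerance = 1e-4)
  expect_equal(musc$rd, 1.2e-3)
  expect_equal(musc$fa, 0.1715, tolerance = 1e-3)
  zero <- tensor_scalars(c(0, 0, 0))
  expect_equal(zero$fa, 0)
  expect_true(zero$degenerate_flag)
})

test_that("SNR measurement follows the mean/sd definition and its invariances", {
  img <- matrix(10, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  set.seed(1)
  noise <- rnorm(4000, 0, 2)
  expect_equal(measure_snr(img, mask, noise), 10 / sd(noise))
  expect_equal(measure_snr(img, mask, noise), 5, tolerance = 0.05)
  # scale invariance
  expect_equal(measure_snr(3 * img, mask, 3 * noise), measure_snr(img, mask, noise))
  expect_error(measure_snr(img, mask, rep(1, 10)), "zero noise")
})

test_that("generator round trip: measured b0 SNR matches the requested 92", {
  lab <- as_fiber_label_map(matrix(1L, 2000, 2000), 1)   # 2 mm homogeneous
  dwi <- synthesize_dwi(lab, list(kappa = 0), pgse_protocol(directions = 6),
                        voxel_size_mm = 0.25, snr_b0 = 92, seed = 5,
                        n_walkers_per_voxel = 50, n_background = 4000)
  b0 <- dwi$signals[, , 1]
  snr_hat <- measure_snr(b0, matrix(TRUE, nrow(b0), ncol(b0)),
                         dwi$background[, 1], noise_type = "rayleigh")
  expect_lt(abs(snr_hat - 92) / 92, 0.10)
})

test_that("local-PCA denoising passes noiseless data through and recovers sigma", {
  set.seed(9)
  pr <- pgse_protocol()
  nx <- 12; ny <- 12
  evs <- c(1.6, 1.1, 1.1) * 1e-3
  sig <- signals_for_tensor(diag(evs), pr)
  clean <- array(rep(sig$signals, each = nx * ny), c(nx, ny, 35))
  dwi0 <- structure(list(signals = clean, bvals = sig$bvals, bvecs = sig$bvecs,
                         voxel_size_mm = 0.5, noise_sigma = 0, background = NULL),
                    class = "dwi_volume")
  den0 <- lpca_denoise(dwi0, patch_radius = 2)
  expect_equal(den0$signals, clean, tolerance = 1e-6)
  sigma <- 1 / 46
  noisy <- dwi0
  noisy$signals <- sqrt((clean + array(rnorm(length(clean), 0, sigma), dim(clean)))^2 +
                          array(rnorm(length(clean), 0, sigma), dim(clean))^2)
  den <- lpca_denoise(noisy, patch_radius = 2)
  # sigma from 25-voxel patches is noisier than the residual itself
  expect_lt(abs(median(den$sigma_map) - sigma) / sigma, 0.25)
  # residual RMS close to the injected noise level
  rms <- sqrt(mean((noisy$signals - den$signals)^2))
  expect_lt(abs(rms - sigma) / sigma, 0.15)
})

test_that("denoising lowers FA error at the study's 0.25 mm b500 SNR", {
  set.seed(31)
  pr <- pgse_protocol()
  nx <- 10; ny <- 10
  evs <- muscle_tensor_eigenvalues()
  sig <- signals_for_tensor(diag(evs), pr)
  clean <- array(rep(sig$signals, each = nx * ny), c(nx, ny, 35))
  sigma <- 1 / 46
  noisy <- structure(list(signals = sqrt((clean + array(rnorm(length(clean), 0, sigma),
                                                        dim(clean)))^2 +
                                           array(rnorm(length(clean), 0, sigma),
                                                 dim(clean))^2),
                          bvals = sig$bvals, bvecs = sig$bvecs,
                          voxel_size_mm = 0.5, noise_sigma = sigma,
                          background = NULL),
                     class = "dwi_volume")
  tf_raw <- fit_tensor_field(noisy)
  tf_den <- fit_tensor_field(lpca_denoise(noisy, patch_radius = 2))
  fa_true <- tensor_scalars(evs)$fa
  rmse_raw <- sqrt(mean((tf_raw$fa - fa_true)^2, na.rm = TRUE))
  rmse_den <- sqrt(mean((tf_den$fa - fa_true)^2, na.rm = TRUE))
  expect_lt(rmse_den, rmse_raw)
})

test_that("noise-free accuracy simulation reports near-zero bias", {
  b <- snr_accuracy_simulation(muscle_tensor_eigenvalues(), snr_b0 = Inf,
                               n_reps = 100, seed = 2)
  expect_true(all(abs(b$bias_pct) < 1e-8))
  expect_error(snr_accuracy_simulation(muscle_tensor_eigenvalues(), snr_b0 = -1,
                                       n_reps = 100), "snr")
  expect_error(snr_accuracy_simulation(muscle_tensor_eigenvalues(), snr_b0 = 25,
                                       n_reps = 10), "n_reps")
})

test_that("FA bias under Rician noise is non-negative for near-isotropic truth", {
  b <- snr_accuracy_simulation(c(1.05, 1.0, 0.95) * 1e-3, snr_b0 = 40,
                               n_reps = 500, seed = 3)
  expect_gt(b$bias_pct[b$metric == "FA"], 0)
})
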