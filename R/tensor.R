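#' Scalar invariants from diffusion tensor eigenvalues
#'
#' MD = (l1+l2+l3)/3, RD = (l2+l3)/2, FA is the normalized eigenvalue
#' standard deviation, FA = sqrt(1/2) sqrt((l1-l2)^2 + (l2-l3)^2 +
#' (l3-l1)^2) / sqrt(l1^2 + l2^2 + l3^2). An all-zero tensor gets FA = 0 and
#' is flagged.
#'
#' @param eigenvalues Numeric length-3 vector or n x 3 matrix; sorted in
#'   decreasing order per row (sorted internally if not).
#' @return A tibble with `fa`, `md`, `rd`, `lambda1` and `degenerate_flag`.
#' @export
tensor_scalars <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, 1)
  stop_if_not_(ncol(ev) == 3, "eigenvalues must have 3 columns")
  ev <- t(apply(ev, 1, sort, decreasing = TRUE))
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  ss <- l1^2 + l2^2 + l3^2
  num <- sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2)
  fa <- ifelse(ss > 0, sqrt(0.5) * num / sqrt(ss), 0)
  tibble(fa = fa, md = (l1 + l2 + l3) / 3, rd = (l2 + l3) / 2, lambda1 = l1,
         degenerate_flag = ss == 0)
}

# Design matrix mapping [ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz] to ln S.
tensor_design_ <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1, -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor in one voxel
#'
#' Weighted linear least squares on log-signals, ln S = ln S0 - b g' D g,
#' with squared-signal weights to undo the heteroscedasticity the log
#' transform induces on Rician data (plain OLS is available). The b = 0
#' images are averaged into a single design row by default. Negative
#' eigenvalues are clamped to a small positive floor (1e-7 mm2/s) and the
#' voxel flagged.
#'
#' @param signals Per-image signals (positive).
#' @param bvals b-values (s/mm2), same length.
#' @param bvecs n x 3 unit directions (rows for b = 0 are ignored).
#' @param weighted Use signal^2-weighted LS (default) or OLS.
#' @param average_b0 Average the b = 0 images before fitting.
#' @param clamp_floor Eigenvalue floor (mm2/s).
#' @return A list: `tensor` (symmetric 3 x 3, mm2/s), `eigenvalues`
#'   (decreasing), `s0`, scalars (`fa`, `md`, `rd`, `lambda1`),
#'   `clamped_flag`, `ok`, `reason`.
#' @export
fit_tensor <- function(signals, bvals, bvecs, weighted = TRUE,
                       average_b0 = TRUE, clamp_floor = 1e-7) {
  stop_if_not_(length(signals) == length(bvals) && nrow(bvecs) == length(bvals),
               "signals, bvals, bvecs must agree in length")
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    return(list(ok = FALSE, reason = "non-positive signal",
                tensor = matrix(NA_real_, 3, 3), eigenvalues = rep(NA_real_, 3),
                fa = NA_real_, md = NA_real_, rd = NA_real_,
                lambda1 = NA_real_, clamped_flag = NA))
  }
  b0 <- bvals == 0
  stop_if_not_(sum(!b0) >= 6, "at least 6 diffusion-weighted images required")
  stop_if_not_(sum(b0) >= 1, "at least one b = 0 image required")
  if (average_b0 && sum(b0) > 1) {
    s <- c(mean(signals[b0]), signals[!b0])
    bv <- c(0, bvals[!b0])
    gv <- rbind(c(0, 0, 0), bvecs[!b0, , drop = FALSE])
    wmult <- c(sum(b0), rep(1, sum(!b0)))   # averaged row has n-fold precision
  } else {
    s <- signals; bv <- bvals; gv <- bvecs
    wmult <- rep(1, length(s))
  }
  # b in s/mm2 with D in mm2/s: product dimensionless, no conversion needed
  X <- tensor_design_(bv, gv)
  y <- log(s)
  w <- if (weighted) s^2 * wmult else wmult
  XtW <- t(X * w)
  M <- XtW %*% X
  if (rcond_(M) < 1e-12) abort("rank-deficient diffusion-encoding design")
  theta <- solve(M, XtW %*% y)
  Dmat <- matrix(c(theta[2], theta[5], theta[6],
                   theta[5], theta[3], theta[7],
                   theta[6], theta[7], theta[4]), 3, 3)
  ev <- eigen(Dmat, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  clamped <- any(ev < 0)
  ev <- pmax(ev, clamp_floor)
  sc <- tensor_scalars(ev)
  list(ok = TRUE, reason = NA_character_, tensor = Dmat, eigenvalues = ev,
       s0 = exp(theta[1]), fa = sc$fa, md = sc$md, rd = sc$rd,
       lambda1 = sc$lambda1, clamped_flag = clamped)
}

rcond_ <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (max(s) == 0) 0 else min(s) / max(s)
}

#' Fit the diffusion tensor over a DWI volume
#'
#' @param dwi A `dwi_volume`.
#' @param ... Passed to [fit_tensor()].
#' @return A `tensor_field`: `fa`, `md`, `rd`, `lambda1` matrices (voxel
#'   grid), `eigenvalues` (nx x ny x 3), `fit_mask`, `clamped` flags, and the
#'   voxel size. Signals must be in mm2/s-compatible units (b in s/mm2).
#' @export
fit_tensor_field <- function(dwi, ...) {
  d <- dim(dwi$signals)
  fa <- md <- rd <- l1 <- matrix(NA_real_, d[1], d[2])
  evs <- array(NA_real_, c(d[1], d[2], 3))
  mask <- clamped <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      ft <- fit_tensor(dwi$signals[i, j, ], dwi$bvals, dwi$bvecs, ...)
      if (isTRUE(ft$ok)) {
        fa[i, j] <- ft$fa; md[i, j] <- ft$md; rd[i, j] <- ft$rd
        l1[i, j] <- ft$lambda1
        evs[i, j, ] <- ft$eigenvalues
        mask[i, j] <- TRUE
        clamped[i, j] <- ft$clamped_flag
      }
    }
  }
  structure(list(fa = fa, md = md, rd = rd, lambda1 = l1, eigenvalues = evs,
                 fit_mask = mask, clamped = clamped,
                 voxel_size_mm = dwi$voxel_size_mm),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d x %d voxels @ %.3g mm, %d fitted (%d clamped)\n",
              nrow(x$fa), ncol(x$fa), x$voxel_size_mm, sum(x$fit_mask),
              sum(x$clamped)))
  invisible(x)
}

#' @export
tidy.tensor_field <- function(x, ...) {
  d <- dim(x$fa)
  tibble(voxel_x = rep(seq_len(d[1]), d[2]),
         voxel_y = rep(seq_len(d[2]), each = d[1]),
         fa = as.vector(x$fa), md = as.vector(x$md), rd = as.vector(x$rd),
         lambda1 = as.vector(x$lambda1),
         fitted = as.vector(x$fit_mask), clamped = as.vector(x$clamped))
}

#' Local-PCA denoising of a DWI stack
#'
#' Sliding-window principal component analysis over image space with
#' Marchenko-Pastur noise-level eigenvalue thresholding: in each patch the
#' image-dimension covariance spectrum is split into noise and signal
#' components, noise components are discarded, and the centre voxel is
#' reconstructed from the retained ones. Noiseless data pass through
#' unchanged (nothing is below the threshold). Output is clipped at zero.
#'
#' @param dwi A `dwi_volume`.
#' @param patch_radius Patch half-width in voxels (patch is
#'   `(2r+1) x (2r+1)`).
#' @return A `dwi_volume` with denoised signals; per-voxel noise estimates in
#'   `sigma_map`.
#' @export
lpca_denoise <- function(dwi, patch_radius = 2) {
  d <- dim(dwi$signals)
  n_img <- d[3]
  stop_if_not_(n_img >= 7, "at least 6 + 1 images per voxel required")
  r <- as.integer(patch_radius)
  stop_if_not_(2 * r + 1 <= d[1] && 2 * r + 1 <= d[2],
               "patch larger than volume")
  out <- array(NA_real_, d)
  sigma_map <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    i0 <- min(max(i - r, 1), d[1] - 2 * r)
    for (j in seq_len(d[2])) {
      j0 <- min(max(j - r, 1), d[2] - 2 * r)
      block <- dwi$signals[i0:(i0 + 2 * r), j0:(j0 + 2 * r), , drop = FALSE]
      X <- matrix(block, ncol = n_img)           # M voxels x N images
      M <- nrow(X)
      mu <- colMeans(X)
      Xc <- sweep(X, 2, mu)
      sv <- svd(Xc)
      lam <- sv$d^2 / M                           # covariance eigenvalues, desc
      mp <- mp_cut_(lam, M, n_img)
      keep <- seq_len(mp$p)
      rec <- if (mp$p == 0) matrix(0, M, n_img) else
        sv$u[, keep, drop = FALSE] %*% (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
      rec <- sweep(rec, 2, mu, `+`)
      ci <- i - i0 + 1; cj <- j - j0 + 1
      out[i, j, ] <- pmax(rec[(cj - 1) * (2 * r + 1) + ci, ], 0)
      sigma_map[i, j] <- sqrt(max(mp$sigma2, 0))
    }
  }
  res <- dwi
  res$signals <- out
  res$sigma_map <- sigma_map
  res
}

# Marchenko-Pastur split of a descending covariance spectrum: returns the
# number of signal components p and the noise variance estimate.
mp_cut_ <- function(lam, M, N) {
  R <- length(lam)
  for (p in 0:(R - 1)) {
    tail <- lam[(p + 1):R]
    sigma2 <- mean(tail)
    gamma <- (N - p) / M
    edge <- sigma2 * (1 + sqrt(gamma))^2          # MP upper bulk edge
    if (lam[p + 1] <= edge) return(list(p = p, sigma2 = sigma2))
  }
  list(p = R, sigma2 = 0)
}

#' Measure image SNR
#'
#' SNR is the mean signal over the tissue mask divided by the standard
#' deviation of the noise. When the noise region is magnitude (Rayleigh)
#' background air, its standard deviation understates the Gaussian channel
#' sigma by sqrt((4 - pi) / 2); `noise_type = "rayleigh"` applies that
#' correction.
#'
#' @param image Numeric matrix/array.
#' @param tissue_mask Logical mask, same shape.
#' @param noise_region Numeric vector/matrix of noise samples (disjoint from
#'   the tissue).
#' @param noise_type `"gaussian"` (plain sd) or `"rayleigh"` (magnitude
#'   background).
#' @return SNR (scalar).
#' @export
measure_snr <- function(image, tissue_mask, noise_region,
                        noise_type = c("gaussian", "rayleigh")) {
  noise_type <- match.arg(noise_type)
  stop_if_not_(any(tissue_mask), "empty tissue mask")
  stop_if_not_(length(noise_region) > 1, "empty noise region")
  s <- sd(as.vector(noise_region))
  stop_if_not_(s > 0, "zero noise standard deviation")
  if (noise_type == "rayleigh") s <- s / sqrt((4 - pi) / 2)
  mean(image[tissue_mask]) / s
}

#' SNR-versus-accuracy Monte-Carlo for DTI metrics
#'
#' Simulates the noiseless protocol signals for a ground-truth tensor, adds
#' Rician noise at the requested b = 0 SNR over many repetitions, refits the
#' tensor each time, and reports the relative error of the mean FA, MD and RD
#' against truth together with their dispersion. This is the experiment
#' behind the design rule that SNR must reach ~25 for 5% accuracy and ~50
#' for 1%.
#'
#' @param truth_eigenvalues Length-3 ground-truth eigenvalues (mm2/s),
#'   decreasing; the tensor is diagonal in the lab frame.
#' @param protocol A [pgse_protocol()].
#' @param snr_b0 b = 0 SNR (> 0; Inf allowed).
#' @param n_reps Repetitions (>= 100).
#' @param seed RNG seed.
#' @param denoise Apply nothing (placeholder for pipeline parity); the cited
#'   thresholds predate denoising, so this simulation uses raw signals.
#' @param ... Passed to [fit_tensor()].
#' @return A `bias_table` tibble: per metric the truth, mean and sd of the
#'   estimates, relative bias of the mean (%), and rep count.
#' @export
snr_accuracy_simulation <- function(truth_eigenvalues, protocol = pgse_protocol(),
                                    snr_b0, n_reps = 2000, seed = 1L, ...) {
  stop_if_not_(snr_b0 > 0, "snr_b0 must be > 0")
  stop_if_not_(n_reps >= 100, "n_reps must be >= 100")
  ev <- sort(truth_eigenvalues, decreasing = TRUE)
  Dtruth <- diag(ev)
  ndir <- nrow(protocol$directions)
  bvals <- c(rep(0, protocol$n_b0), rep(protocol$b_s_per_mm2, ndir))
  bvecs <- rbind(matrix(0, protocol$n_b0, 3), protocol$directions)
  # noiseless normalized signals; b (s/mm2) x D (mm2/s) is dimensionless
  adc <- rowSums((bvecs %*% Dtruth) * bvecs)
  s_clean <- exp(-bvals * adc)
  sigma <- if (is.infinite(snr_b0)) 0 else 1 / snr_b0
  n_img <- length(s_clean)
  truth_sc <- tensor_scalars(ev)
  est <- matrix(NA_real_, n_reps, 3)
  with_seed_(seed, {
    for (rep in seq_len(n_reps)) {
      s <- if (sigma == 0) s_clean else
        sqrt((s_clean + rnorm(n_img, 0, sigma))^2 + rnorm(n_img, 0, sigma)^2)
      ft <- fit_tensor(s, bvals, bvecs, ...)
      if (isTRUE(ft$ok)) est[rep, ] <- c(ft$fa, ft$md, ft$rd)
    }
  })
  truth_v <- c(truth_sc$fa, truth_sc$md, truth_sc$rd)
  mean_est <- colMeans(est, na.rm = TRUE)
  out <- tibble(metric = c("FA", "MD", "RD"), truth = truth_v,
                mean_estimate = mean_est,
                sd_estimate = apply(est, 2, sd, na.rm = TRUE),
                bias_pct = 100 * (mean_est - truth_v) / truth_v,
                n_reps = n_reps, snr_b0 = snr_b0)
  class(out) <- c("bias_table", class(out))
  out
}

#' Eigenvalues of a muscle-like tensor with given FA
#'
#' Solves for axially symmetric eigenvalues (l2 = l3) that combine a fixed
#' axial diffusivity with a target FA.
#'
#' @param lambda1 Axial diffusivity (mm2/s).
#' @param fa Target fractional anisotropy.
#' @return Length-3 eigenvalue vector (decreasing).
#' @export
muscle_tensor_eigenvalues <- function(lambda1 = 1.6e-3, fa = 0.25) {
  f <- function(l2) (lambda1 - l2) / sqrt(lambda1^2 + 2 * l2^2) - fa
  l2 <- stats::uniroot(f, c(1e-9, lambda1 - 1e-12), tol = 1e-15)$root
  c(lambda1, l2, l2)
}
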