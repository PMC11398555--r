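# Shared fixtures, built in code at test time.

small_packing <- function(seed = 7, mean_d = 30, cv = 0.3, ...) {
  p <- fiber_packing_params(region_width_um = 400, region_height_um = 400,
                            mean_diameter_um = mean_d, diameter_cv = cv,
                            seed = seed, ...)
  generate_fiber_packing(p, pixel_size_um = 0.75)
}

# Noiseless PGSE signals for a diagonal-frame tensor under a protocol.
signals_for_tensor <- function(D, protocol = pgse_protocol()) {
  bvals <- c(rep(0, protocol$n_b0), rep(protocol$b_s_per_mm2, nrow(protocol$directions)))
  bvecs <- rbind(matrix(0, protocol$n_b0, 3), protocol$directions)
  adc <- rowSums((bvecs %*% D) * bvecs)
  list(signals = exp(-bvals * adc), bvals = bvals, bvecs = bvecs)
}

random_spd_tensor <- function() {
  ev <- sort(runif(3, 0.3e-3, 2.5e-3), decreasing = TRUE)
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  Q %*% diag(ev) %*% t(Q)
}

# ellipse mask in mm for registration tests
ellipse_mask <- function(cx, cy, ax, ay, n = 80, px_mm = 0.5, theta = 0) {
  xs <- (seq_len(n) - 0.5) * px_mm
  m <- matrix(0, n, n)
  ct <- cos(theta); st <- sin(theta)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- xs[j] - cx; dy <- xs[i] - cy
    u <- ct * dx + st * dy; v <- -st * dx + ct * dy
    m[i, j] <- (u / ax)^2 + (v / ay)^2 <= 1
  }
  m
}
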