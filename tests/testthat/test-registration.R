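test_that("boundary extraction matches closed forms for disc and square", {
  n <- 120; px <- 0.25                       # 30 mm field
  xs <- (seq_len(n) - 0.5) * px
  disc <- outer(xs, xs, function(y, x) (x - 15)^2 + (y - 15)^2 <= 10^2)
  bc <- extract_boundary(disc, px)
  expect_equal(boundary_length(bc), 2 * pi * 10, tolerance = 0.02)
  sq <- matrix(0, n, n); sq[21:100, 21:100] <- 1    # 20 mm square
  bs <- extract_boundary(sq, px)
  expect_equal(abs(attr(bs, "area_mm2")), 20^2, tolerance = 0.02)
  expect_error(extract_boundary(matrix(0, 10, 10), 1), "empty")
})

test_that("two similar-size components are refused with a report", {
  n <- 100; xs <- (seq_len(n) - 0.5) * 0.5
  two <- outer(xs, xs, function(y, x)
    (x - 12)^2 + (y - 25)^2 <= 8^2 | (x - 36)^2 + (y - 25)^2 <= 8^2)
  expect_error(extract_boundary(two, 0.5), "similar-size")
})

test_that("registering identical contours is the identity", {
  m <- ellipse_mask(20, 20, 12, 7)
  b <- extract_boundary(m, 0.5)
  tr <- register_boundaries(b, b)
  expect_lt(tr$rms_residual_mm, 1e-6)
  expect_equal(tr$mean_displacement_mm, c(0, 0), tolerance = 1e-9)
})

test_that("a known translation is recovered within 0.05 mm", {
  fixed <- extract_boundary(ellipse_mask(20, 20, 12, 7), 0.5)
  moving <- extract_boundary(ellipse_mask(17, 22, 12, 7), 0.5)   # off by (-3, +2)
  tr <- register_boundaries(moving, fixed)
  expect_lt(max(abs(tr$mean_displacement_mm - c(3, -2))), 0.05)
  expect_lt(tr$rms_residual_mm, 0.05)
})

test_that("an affinely sheared ellipse registers with small residual", {
  fixed <- extract_boundary(ellipse_mask(20, 20, 12, 7), 0.5)
  sheared <- extract_boundary(ellipse_mask(20, 20, 12, 7, theta = 0.35), 0.5)
  tr <- register_boundaries(sheared, fixed)
  expect_lt(tr$rms_residual_mm, 0.05 * boundary_length(fixed))
  # adding landmarks cannot worsen the noiseless boundary residual (much)
  tr_more <- register_boundaries(sheared, fixed, n_landmarks = 160)
  expect_lte(tr_more$rms_residual_mm, tr$rms_residual_mm * 1.05)
})

test_that("degenerate contours are refused", {
  line <- tibble::tibble(x_mm = seq(0, 1, length.out = 10), y_mm = rep(1, 10))
  expect_error(register_boundaries(line, line), "degenerate")
})

test_that("grid resampling: identity, 2x2 kernel, and warp round trip", {
  mk_maps <- function(vals) {
    valid <- is.finite(vals)
    structure(list(diameter = vals, area = vals, sv = vals, valid = valid,
                   weight = matrix(as.numeric(valid), nrow(vals)),
                   pixel_size_um = 250),
              class = "morpho_maps")
  }
  const <- mk_maps(matrix(5, 8, 8))
  out <- resample_to_grid(const, NULL, 250)
  expect_equal(out$diameter, matrix(5, 8, 8))
  blk <- mk_maps(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(resample_to_grid(blk, NULL, 500)$diameter[1, 1], 2.5)
  expect_error(resample_to_grid(const, NULL, 300), "non-integer")

  # warp + unwarp round trip on a smooth map
  fixed <- extract_boundary(ellipse_mask(20, 20, 14, 9), 0.5)
  moving <- extract_boundary(ellipse_mask(21, 19, 14, 9), 0.5)
  fwd <- register_boundaries(moving, fixed)
  bwd <- register_boundaries(fixed, moving)
  xs <- (seq_len(40) - 0.5)
  smooth <- outer(xs, xs, function(y, x) 30 + 0.2 * x + 0.1 * y + 0.005 * x * y)
  mm <- mk_maps(smooth); mm$pixel_size_um <- 1000
  once <- resample_to_grid(mm, fwd, 1000)
  back <- resample_to_grid(once, bwd, 1000)
  inner <- 8:32                       # away from edge effects
  rel <- (back$diameter[inner, inner] - smooth[inner, inner]) / smooth[inner, inner]
  expect_lt(sqrt(mean(rel^2, na.rm = TRUE)), 0.01)
})

test_that("contours round-trip through two-column CSV", {
  b <- extract_boundary(ellipse_mask(20, 20, 12, 7), 0.5)
  path <- file.path(tempdir(), "contour.csv")
  write_contour(b, path)
  b2 <- read_contour(path)
  expect_equal(b2$x_mm, b$x_mm, tolerance = 1e-9)
  expect_equal(b2$y_mm, b$y_mm, tolerance = 1e-9)
  expect_error(read_contour({
    p <- file.path(tempdir(), "bad.csv")
    utils::write.csv(data.frame(a = 1:10, b = 1:10), p, row.names = FALSE)
    p
  }), "x_mm")
})

test_that("interpretation bands follow the published scale on |r|", {
  expect_equal(interpret_r(0.13), "negligible")
  expect_equal(interpret_r(0.95), "very high")
  expect_equal(interpret_r(-0.55), "moderate")
  # boundary values promote to the higher band
  expect_equal(interpret_r(c(0.3, 0.5, 0.7, 0.9)),
               c("low", "moderate", "high", "very high"))
  expect_error(interpret_r(1.2), "<= 1")
})

test_that("pixel-wise correlation: exact cases and the product-moment formula", {
  base <- tibble::tibble(diameter = rep(seq(20, 50, length.out = 12), 3),
                         sample = rep(c("a", "b", "c"), each = 12))
  base$area <- pi / 4 * base$diameter^2
  base$sv <- 4 / base$diameter
  px <- dplyr::mutate(base, fa = diameter, md = -diameter, rd = 0.5 + 2 * diameter)
  rep <- pixelwise_correlation(px)
  r_fa_d <- rep$pearson_r[rep$metric_dti == "FA" & rep$metric_histo == "diameter"]
  r_md_d <- rep$pearson_r[rep$metric_dti == "MD" & rep$metric_histo == "diameter"]
  r_rd_d <- rep$pearson_r[rep$metric_dti == "RD" & rep$metric_histo == "diameter"]
  expect_equal(r_fa_d, 1)
  expect_equal(r_md_d, -1)
  expect_equal(r_rd_d, 1)        # affine invariance
  expect_true(all(rep$n_pixels == 36))
  expect_length(rep$per_sample_r[[1]], 3)

  # product-moment closed form on a small vector pair
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  r_hand <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    sqrt((sum(x^2) - length(x) * mean(x)^2) * (sum(y^2) - length(y) * mean(y)^2))
  expect_equal(r_hand, 11 / sqrt(130))
  expect_equal(cor(x, y), r_hand)
})

test_that("zero-variance variables give undefined r, not zero", {
  px <- tibble::tibble(diameter = rep(30, 12), area = rep(700, 12),
                       sv = seq(0.1, 0.2, length.out = 12),
                       fa = seq(0.1, 0.3, length.out = 12),
                       md = rnorm(12, 1e-3, 1e-5), rd = rnorm(12, 1e-3, 1e-5))
  rep <- pixelwise_correlation(px)
  expect_true(is.na(rep$pearson_r[rep$metric_histo == "diameter" &
                                    rep$metric_dti == "FA"]))
  expect_false(is.na(rep$pearson_r[rep$metric_histo == "sv" &
                                     rep$metric_dti == "FA"]))
  expect_error(pixelwise_correlation(px[1:5, ]), "10")
})

test_that("end-to-end identity: a map correlated with itself gives r = 1", {
  m <- small_packing(seed = 41)
  mm <- downsample_masked_mean(paint_morphometry_maps(m, fiber_stats(m)), 50)
  tf <- structure(list(fa = mm$diameter, md = mm$area, rd = mm$sv,
                       lambda1 = mm$diameter,
                       fit_mask = mm$valid, clamped = mm$valid & FALSE,
                       voxel_size_mm = 0.05),
                  class = "tensor_field")
  px <- collect_pixel_data(mm, tf)
  rep <- pixelwise_correlation(px)
  matched <- (rep$metric_dti == "FA" & rep$metric_histo == "diameter") |
    (rep$metric_dti == "MD" & rep$metric_histo == "area") |
    (rep$metric_dti == "RD" & rep$metric_histo == "sv")
  expect_equal(rep$pearson_r[matched], rep(1, 3), tolerance = 1e-12)
})
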