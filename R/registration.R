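#' Extract the muscle boundary contour from a mask
#'
#' Sub-pixel marching-squares contour (level 0.5) of the largest connected
#' region of a binary mask, in physical coordinates (mm). Fails when the mask
#' is empty or when a second component of comparable size exists (the section
#' then needs manual exclusion masks).
#'
#' @param mask Logical/numeric matrix (rows = y, cols = x).
#' @param pixel_size_mm Pixel size (mm).
#' @param source `"histology"` or `"MRI"` (metadata).
#' @return A `boundary_contour`: tibble of closed polyline points
#'   (`x_mm`, `y_mm`), with `source` and shoelace `area_mm2` attributes.
#' @export
extract_boundary <- function(mask, pixel_size_mm, source = c("histology", "MRI")) {
  source <- match.arg(source)
  m <- (mask > 0) * 1
  stop_if_not_(any(m > 0), "empty mask: no boundary to extract")
  # a light binomial blur turns the binary staircase into a smooth field so
  # the marching-squares interpolation lands sub-pixel on the true boundary
  # (a raw binary contour overestimates a circle's length by ~5%)
  m <- blur3_(blur3_(m))
  xs <- (seq_len(ncol(m)) - 0.5) * pixel_size_mm
  ys <- (seq_len(nrow(m)) - 0.5) * pixel_size_mm
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(m), levels = 0.5)
  stop_if_not_(length(cl) > 0, "no contour found at level 0.5")
  areas <- vapply(cl, function(cc) abs(shoelace_(cc$x, cc$y)), numeric(1))
  ord <- order(areas, decreasing = TRUE)
  if (length(cl) > 1 && areas[ord[2]] > 0.5 * areas[ord[1]]) {
    abort(sprintf(
      "multiple similar-size components: areas %s mm2; supply an exclusion mask",
      paste(signif(areas[ord[1:2]], 4), collapse = ", ")))
  }
  best <- cl[[ord[1]]]
  pts <- tibble(x_mm = best$x, y_mm = best$y)
  stop_if_not_(nrow(pts) >= 8, "contour has fewer than 8 points")
  structure(pts, class = c("boundary_contour", class(pts)),
            source = source, area_mm2 = areas[ord[1]],
            pixel_size_mm = pixel_size_mm)
}

# separable 3x3 binomial smoothing with replicated edges
blur3_ <- function(m) {
  pad_r <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  v <- (pad_r[seq_len(nrow(m)), ] + 2 * pad_r[seq_len(nrow(m)) + 1, ] +
          pad_r[seq_len(nrow(m)) + 2, ]) / 4
  pad_c <- cbind(v[, 1, drop = FALSE], v, v[, ncol(v), drop = FALSE])
  (pad_c[, seq_len(ncol(m))] + 2 * pad_c[, seq_len(ncol(m)) + 1] +
      pad_c[, seq_len(ncol(m)) + 2]) / 4
}

shoelace_ <- function(x, y) {
  n <- length(x)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1 }
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

contour_length_ <- function(x, y) {
  n <- length(x)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Write / read a boundary contour as two-column CSV (x_mm, y_mm)
#'
#' @param contour A `boundary_contour` (or tibble with `x_mm`, `y_mm`).
#' @param path CSV path.
#' @return `write_contour()` returns `path` invisibly; `read_contour()`
#'   returns a `boundary_contour`.
#' @export
write_contour <- function(contour, path) {
  utils::write.csv(as.data.frame(contour[, c("x_mm", "y_mm")]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  df <- utils::read.csv(path)
  stop_if_not_(all(c("x_mm", "y_mm") %in% names(df)),
               "contour CSV needs x_mm, y_mm columns")
  stop_if_not_(nrow(df) >= 8, "contour has fewer than 8 points")
  structure(as_tibble(df), class = c("boundary_contour", class(as_tibble(df))),
            source = "imported")
}

#' Total length of a boundary contour (mm)
#' @param contour A `boundary_contour`.
#' @return Perimeter length in mm.
#' @export
boundary_length <- function(contour) {
  contour_length_(contour$x_mm, contour$y_mm)
}

# Resample a closed polyline to n points equally spaced in arc length.
resample_contour_ <- function(x, y, n) {
  m <- length(x)
  if (x[1] != x[m] || y[1] != y[m]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  tot <- s[length(s)]
  tgt <- seq(0, tot, length.out = n + 1)[seq_len(n)]
  out <- cbind(stats::approx(s, x, xout = tgt)$y,
               stats::approx(s, y, xout = tgt)$y)
  dimnames(out) <- NULL
  out
}

# Thin-plate spline fit src (n x 2) -> dst (n x 2); lambda = 0 interpolates.
tps_fit_ <- function(src, dst, lambda = 0) {
  n <- nrow(src)
  d2 <- as.matrix(stats::dist(src))^2
  K <- ifelse(d2 > 0, 0.5 * d2 * log(d2), 0)      # r^2 log r = d2 log(d2)/2
  P <- cbind(1, src)
  L <- rbind(cbind(K + lambda * diag(n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coefs <- solve(L, rhs)
  list(src = src, w = coefs[seq_len(n), , drop = FALSE],
       a = coefs[n + 1:3, , drop = FALSE])
}

tps_apply_ <- function(fit, pts) {
  pts <- as.matrix(pts)
  d2 <- outer(pts[, 1], fit$src[, 1], `-`)^2 + outer(pts[, 2], fit$src[, 2], `-`)^2
  U <- ifelse(d2 > 0, 0.5 * d2 * log(d2), 0)
  cbind(1, pts) %*% fit$a + U %*% fit$w
}

#' Register two muscle boundary contours
#'
#' Boundary-landmark registration as used for histology-to-DTI matching:
#' both closed contours are resampled to `n_landmarks` points equally spaced
#' in arc length, pre-aligned by centroid and RMS-radius scale,
#' correspondence is fixed by the circular shift (and orientation) that
#' minimizes the summed squared distance, and a thin-plate-spline warp is
#' fitted on the matched landmarks (both directions). The residual is the
#' RMS distance from the transformed moving contour, densely resampled, to
#' the fixed contour.
#'
#' @param moving,fixed `boundary_contour` objects (or tibbles with
#'   `x_mm`, `y_mm`).
#' @param n_landmarks Number of matched landmarks.
#' @param lambda TPS regularization (0 = exact interpolation).
#' @return A `boundary_transform`: `forward`/`inverse` TPS fits, matched
#'   `landmarks`, `rms_residual_mm`, and the recovered mean displacement.
#' @export
register_boundaries <- function(moving, fixed, n_landmarks = 80, lambda = 0) {
  mv <- resample_contour_(moving$x_mm, moving$y_mm, n_landmarks)
  fx <- resample_contour_(fixed$x_mm, fixed$y_mm, n_landmarks)
  stop_if_not_(abs(shoelace_(mv[, 1], mv[, 2])) > 1e-9 &&
                 abs(shoelace_(fx[, 1], fx[, 2])) > 1e-9,
               "degenerate (zero-area) contour")
  cm <- colMeans(mv); cf <- colMeans(fx)
  sm <- sqrt(mean(rowSums(sweep(mv, 2, cm)^2)))
  sf <- sqrt(mean(rowSums(sweep(fx, 2, cf)^2)))
  mvn <- sweep(mv, 2, cm) / sm
  fxn <- sweep(fx, 2, cf) / sf
  best <- NULL
  for (rev_orient in c(FALSE, TRUE)) {
    cand <- if (rev_orient) mvn[rev(seq_len(n_landmarks)), ] else mvn
    idx_cand <- if (rev_orient) rev(seq_len(n_landmarks)) else seq_len(n_landmarks)
    for (sh in 0:(n_landmarks - 1)) {
      ord <- c(seq_len(n_landmarks), seq_len(n_landmarks))[(sh + 1):(sh + n_landmarks)]
      ssd <- sum((cand[ord, ] - fxn)^2)
      if (is.null(best) || ssd < best$ssd)
        best <- list(ssd = ssd, ord = idx_cand[ord])
    }
  }
  mv_matched <- mv[best$ord, ]
  forward <- tps_fit_(mv_matched, fx, lambda)
  inverse <- tps_fit_(fx, mv_matched, lambda)
  dense_m <- resample_contour_(moving$x_mm, moving$y_mm, 4 * n_landmarks)
  dense_f <- resample_contour_(fixed$x_mm, fixed$y_mm, 4 * n_landmarks)
  warped <- tps_apply_(forward, dense_m)
  d2 <- outer(warped[, 1], dense_f[, 1], `-`)^2 +
    outer(warped[, 2], dense_f[, 2], `-`)^2
  rms <- sqrt(mean(apply(d2, 1, min)))
  structure(list(forward = forward, inverse = inverse,
                 landmarks = list(moving = mv_matched, fixed = fx),
                 rms_residual_mm = rms,
                 mean_displacement_mm = colMeans(fx - mv_matched)),
            class = "boundary_transform")
}

#' @export
print.boundary_transform <- function(x, ...) {
  cat(sprintf("<boundary_transform> %d landmarks, RMS boundary residual %.4g mm\n",
              nrow(x$landmarks$moving), x$rms_residual_mm))
  invisible(x)
}

#' Warp morphometry maps and resample onto a target grid
#'
#' Applies the inverse transform to each target-grid pixel centre, samples
#' the moving maps by valid-masked bilinear interpolation at the source
#' resolution, then reduces to the target resolution with the masked block
#' mean (e.g. a 2x2 kernel for 0.25 -> 0.5 mm). Masks propagate
#' conservatively: a pixel is valid iff at least one valid source pixel
#' contributed.
#'
#' @param maps A `morpho_maps` object (pixel size in um).
#' @param transform A `boundary_transform` from [register_boundaries()], or
#'   `NULL` for identity.
#' @param target_pixel_size_um Target grid spacing (um); must be an integer
#'   multiple of the source spacing unless `interpolate = TRUE`.
#' @param interpolate Permit non-integer resolution ratios (pure bilinear).
#' @return A `morpho_maps` object on the target grid.
#' @export
resample_to_grid <- function(maps, transform = NULL, target_pixel_size_um,
                             interpolate = FALSE) {
  ratio <- target_pixel_size_um / maps$pixel_size_um
  if (!interpolate)
    stop_if_not_(abs(ratio - round(ratio)) < 1e-9,
                 "non-integer resolution ratio; pass interpolate = TRUE to allow")
  warped <- maps
  if (!is.null(transform)) {
    px_mm <- maps$pixel_size_um / 1000
    nr <- nrow(maps$diameter); nc <- ncol(maps$diameter)
    xy <- cbind(rep((seq_len(nc) - 0.5) * px_mm, each = nr),
                rep((seq_len(nr) - 0.5) * px_mm, nc))
    src <- tps_apply_(transform$inverse, xy)
    warp1 <- function(M) matrix(bilinear_masked_(M, maps$valid,
                                                 src[, 1] / px_mm, src[, 2] / px_mm),
                                nr, nc)
    d <- warp1(maps$diameter); a <- warp1(maps$area); v <- warp1(maps$sv)
    valid <- is.finite(d)
    warped <- new_morpho_maps(d, a, v, valid,
                              weight = matrix(as.numeric(valid), nr, nc),
                              pixel_size_um = maps$pixel_size_um)
  }
  if (abs(ratio - 1) < 1e-9) return(warped)
  if (abs(ratio - round(ratio)) < 1e-9)
    return(downsample_masked_mean(warped, round(ratio)))
  # non-integer ratio: bilinear sample at target centres
  nr2 <- floor(nrow(warped$diameter) / ratio); nc2 <- floor(ncol(warped$diameter) / ratio)
  cx <- (rep(seq_len(nc2), each = nr2) - 0.5) * ratio
  cy <- (rep(seq_len(nr2), nc2) - 0.5) * ratio
  samp <- function(M) matrix(bilinear_masked_(M, warped$valid, cx, cy), nr2, nc2)
  d <- samp(warped$diameter)
  valid <- is.finite(d)
  new_morpho_maps(d, samp(warped$area), samp(warped$sv), valid,
                  weight = matrix(as.numeric(valid), nr2, nc2),
                  pixel_size_um = target_pixel_size_um)
}

# Valid-masked bilinear interpolation; x, y in pixel units (centres at
# i - 0.5). Returns NA where no valid neighbour contributes.
bilinear_masked_ <- function(M, valid, x, y) {
  nr <- nrow(M); nc <- ncol(M)
  jf <- x - 0.5; if_ <- y - 0.5
  j0 <- floor(jf); i0 <- floor(if_)
  fj <- jf - j0; fi <- if_ - i0
  out <- numeric(length(x))
  wsum <- numeric(length(x))
  vsum <- numeric(length(x))
  for (dj in 0:1) {
    for (di in 0:1) {
      jj <- j0 + dj + 1L; ii <- i0 + di + 1L
      wt <- (dj * fj + (1 - dj) * (1 - fj)) * (di * fi + (1 - di) * (1 - fi))
      ok <- jj >= 1 & jj <= nc & ii >= 1 & ii <= nr
      idx <- ifelse(ok, (jj - 1L) * nr + ii, 1L)
      vv <- valid[idx] & ok
      contrib <- ifelse(vv, M[idx], 0)
      vsum <- vsum + ifelse(vv, wt * contrib, 0)
      wsum <- wsum + ifelse(vv, wt, 0)
    }
  }
  ifelse(wsum > 0, vsum / wsum, NA_real_)
}

#' Interpret a Pearson correlation coefficient
#'
#' Banding on |r|: 0-0.29 negligible, 0.3-0.49 low, 0.5-0.69 moderate,
#' 0.7-0.89 high, 0.9-1.0 very high; boundary values go to the higher band.
#'
#' @param r Correlation value(s), |r| <= 1 (NA passes through).
#' @return Character vector of categories.
#' @export
interpret_r <- function(r) {
  stop_if_not_(all(abs(r) <= 1 + 1e-12, na.rm = TRUE), "|r| must be <= 1")
  a <- abs(r)
  c("negligible", "low", "moderate", "high", "very high")[as.integer(
    cut(a, breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf), right = FALSE))]
}

#' Pixel-wise correlation between DTI and histologic metrics
#'
#' Computes the pooled Pearson correlation for each of the nine
#' (FA, MD, RD) x (diameter, area, S/V) pairs over co-localized valid
#' pixels, with the interpretation banding applied to |r|. Zero variance in
#' either variable yields `NA` (reported as undefined, not 0). Per-sample
#' correlations are included when a `sample` column is present.
#'
#' @param pixels A tibble of co-localized pixel values with columns
#'   `fa`, `md`, `rd`, `diameter`, `area`, `sv` and optionally `sample`
#'   (see [collect_pixel_data()]).
#' @return A `correlation_report` tibble: one row per metric pair with
#'   `pearson_r`, `n_pixels`, `interpretation` and (if samples are present)
#'   a `per_sample_r` list column.
#' @export
pixelwise_correlation <- function(pixels) {
  need <- c("fa", "md", "rd", "diameter", "area", "sv")
  stop_if_not_(all(need %in% names(pixels)), "pixels must contain fa, md, rd, diameter, area, sv")
  px <- pixels[complete.cases(pixels[, need]), ]
  stop_if_not_(nrow(px) >= 10, "fewer than 10 valid co-localized pixels")
  pairs <- expand.grid(metric_dti = c("fa", "md", "rd"),
                       metric_histo = c("diameter", "area", "sv"),
                       stringsAsFactors = FALSE)
  one <- function(md, mh) {
    x <- px[[mh]]; y <- px[[md]]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  r <- mapply(one, pairs$metric_dti, pairs$metric_histo)
  out <- tibble(metric_dti = toupper(pairs$metric_dti),
                metric_histo = pairs$metric_histo,
                n_pixels = nrow(px),
                pearson_r = as.numeric(r),
                interpretation = interpret_r(as.numeric(r)))
  if ("sample" %in% names(px) && length(unique(px$sample)) > 1) {
    out$per_sample_r <- lapply(seq_len(nrow(pairs)), function(k) {
      vapply(split(px, px$sample), function(d) {
        x <- d[[pairs$metric_histo[k]]]; y <- d[[pairs$metric_dti[k]]]
        if (nrow(d) < 3 || sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
      }, numeric(1))
    })
  }
  class(out) <- c("correlation_report", class(out))
  attr(out, "pixels") <- px
  out
}

#' @export
glance.correlation_report <- function(x, ...) {
  tibble(max_abs_r = max(abs(x$pearson_r), na.rm = TRUE),
         n_pixels = x$n_pixels[1],
         n_pairs = nrow(x),
         worst_interpretation = x$interpretation[which.max(abs(x$pearson_r))])
}

#' Collect co-localized pixel data from maps
#'
#' Joins down-sampled morphometry maps and a fitted tensor field on a shared
#' voxel grid, keeping pixels that are valid in the histology maps, fitted by
#' the tensor stage and (by default) free of clamped eigenvalues.
#'
#' @param morpho A `morpho_maps` object on the DTI voxel grid.
#' @param tensors A `tensor_field` of the same grid shape.
#' @param sample Optional sample/location identifier.
#' @param drop_clamped Exclude voxels whose tensor fit clamped an eigenvalue.
#' @return A tibble with columns `sample`, `voxel_x`, `voxel_y`, `diameter`,
#'   `area`, `sv`, `fa`, `md`, `rd`.
#' @export
collect_pixel_data <- function(morpho, tensors, sample = "s1",
                               drop_clamped = TRUE) {
  sm <- dim(morpho$diameter); st <- dim(tensors$fa)
  n <- pmin(sm, st)
  ii <- seq_len(n[1]); jj <- seq_len(n[2])
  keep <- morpho$valid[ii, jj] & tensors$fit_mask[ii, jj]
  if (drop_clamped) keep <- keep & !tensors$clamped[ii, jj]
  idx <- which(keep)
  tibble(sample = sample,
         voxel_x = ((idx - 1L) %% n[1]) + 1L,
         voxel_y = ((idx - 1L) %/% n[1]) + 1L,
         diameter = morpho$diameter[ii, jj][idx],
         area = morpho$area[ii, jj][idx],
         sv = morpho$sv[ii, jj][idx],
         fa = tensors$fa[ii, jj][idx],
         md = tensors$md[ii, jj][idx],
         rd = tensors$rd[ii, jj][idx])
}
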