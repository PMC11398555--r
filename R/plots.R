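#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   geom_text facet_grid facet_wrap labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

raster_df_ <- function(M, px, value_name) {
  idx <- which(is.finite(M))
  tibble(x = (((idx - 1L) %/% nrow(M)) + 0.5) * px,
         y = (((idx - 1L) %% nrow(M)) + 0.5) * px,
         value = M[idx]) |>
    setNames(c("x", "y", value_name))
}

#' Plot per-pixel morphometry maps
#'
#' @param object A `morpho_maps` object.
#' @param metric `"diameter"`, `"area"` or `"sv"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morpho_maps <- function(object, metric = c("diameter", "area", "sv"), ...) {
  metric <- match.arg(metric)
  lab <- c(diameter = "equivalent diameter (µm)",
           area = "cross-sectional area (µm²)",
           sv = "S/V ratio (1/µm)")[[metric]]
  df <- raster_df_(object[[metric]], object$pixel_size_um, "value")
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = lab) +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}

#' Plot DTI scalar maps from a tensor field
#'
#' @param object A `tensor_field`.
#' @param metric `"fa"`, `"md"`, `"rd"` or `"lambda1"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tensor_field <- function(object, metric = c("fa", "md", "rd", "lambda1"), ...) {
  metric <- match.arg(metric)
  df <- raster_df_(object[[metric]], object$voxel_size_mm, "value")
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = toupper(metric)) +
    labs(x = "x (mm)", y = "y (mm)") +
    theme_minimal()
}

#' Combined DTI-vs-histology scatter plots
#'
#' One panel per (DTI metric x histology metric) pair with the pooled
#' Pearson r annotated, mirroring the combined scatter-plot presentation of
#' co-localized data.
#'
#' @param object A `correlation_report` (from [pixelwise_correlation()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_report <- function(object, ...) {
  px <- attr(object, "pixels")
  stop_if_not_(!is.null(px), "report carries no scatter data")
  long <- tidyr::pivot_longer(px, cols = c("fa", "md", "rd"),
                              names_to = "metric_dti", values_to = "dti") |>
    tidyr::pivot_longer(cols = c("diameter", "area", "sv"),
                        names_to = "metric_histo", values_to = "histo")
  ann <- as_tibble(object)[, c("metric_dti", "metric_histo", "pearson_r")]
  ann$metric_dti <- tolower(ann$metric_dti)
  ann$label <- sprintf("r = %.2f", ann$pearson_r)
  ggplot(long, aes(x = .data$histo, y = .data$dti)) +
    geom_point(alpha = 0.25, size = 0.5) +
    facet_grid(metric_dti ~ metric_histo, scales = "free") +
    geom_text(data = ann, aes(label = .data$label), x = -Inf, y = Inf,
              hjust = -0.1, vjust = 1.5, inherit.aes = FALSE) +
    labs(x = "histologic metric", y = "DTI metric") +
    theme_minimal()
}

#' Plot a relaxometry fit
#'
#' @param object A `relax_fit`.
#' @param ... Unused.
#' @return A ggplot of the data and fitted decay/recovery curve.
#' @export
autoplot.relax_fit <- function(object, ...) {
  t <- object$series$times_ms
  tt <- seq(min(t), max(t), length.out = 200)
  pred <- if (object$model == "t1_saturation_recovery")
    object$s0 * (1 - exp(-tt / object$tau_ms))
  else object$s0 * exp(-tt / object$tau_ms)
  ggplot(tibble(t = t, s = object$series$signals), aes(x = .data$t, y = .data$s)) +
    geom_point() +
    geom_line(data = tibble(t = tt, s = pred), colour = "steelblue") +
    labs(x = if (object$model == "t1_saturation_recovery") "TR (ms)" else "TE (ms)",
         y = "signal (a.u.)") +
    theme_minimal()
}

#' Plot an SNR-accuracy bias table
#'
#' @param object A `bias_table` from [snr_accuracy_simulation()] (rows from
#'   several SNRs may be bound together).
#' @param ... Unused.
#' @return A ggplot of relative bias per metric against SNR.
#' @export
autoplot.bias_table <- function(object, ...) {
  ggplot(object, aes(x = .data$snr_b0, y = abs(.data$bias_pct),
                     colour = .data$metric)) +
    geom_point() + geom_line() +
    labs(x = "b0 SNR", y = "|relative bias| of mean estimate (%)") +
    theme_minimal()
}
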