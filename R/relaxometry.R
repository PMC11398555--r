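#' Relaxometry series container
#'
#' @param times_ms Strictly increasing TR or TE values (ms); at least 3
#'   points for a 2-parameter fit.
#' @param signals Matching signal magnitudes (a.u.).
#' @param mode `"T1_vtr"` (saturation-recovery, variable TR) or `"T2_cpmg"`
#'   (CPMG echo train).
#' @return A `relax_series` object.
#' @export
relax_series <- function(times_ms, signals, mode = c("T1_vtr", "T2_cpmg")) {
  mode <- match.arg(mode)
  stop_if_not_(length(times_ms) == length(signals), "times and signals must match")
  stop_if_not_(length(times_ms) >= 3, "at least 3 points required for a 2-parameter fit")
  stop_if_not_(all(diff(times_ms) > 0), "times must be strictly increasing")
  structure(list(times_ms = as.numeric(times_ms), signals = as.numeric(signals),
                 mode = mode),
            class = "relax_series")
}

new_relax_fit <- function(series, s0, tau, model, residuals, flags) {
  structure(list(series = series, s0 = s0, tau_ms = tau, model = model,
                 residuals = residuals, rss = sum(residuals^2),
                 flags = flags),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  lab <- if (x$model == "t1_saturation_recovery") "T1" else "T2"
  cat(sprintf("<relax_fit> %s = %.4g ms, S0 = %.4g, RSS = %.3g%s\n",
              lab, x$tau_ms, x$s0, x$rss,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @export
tidy.relax_fit <- function(x, ...) {
  tibble(term = c("S0", if (x$model == "t1_saturation_recovery") "T1_ms" else "T2_ms"),
         estimate = c(x$s0, x$tau_ms))
}

#' @export
glance.relax_fit <- function(x, ...) {
  tibble(model = x$model, tau_ms = x$tau_ms, s0 = x$s0, rss = x$rss,
         n = length(x$series$times_ms),
         flagged = length(x$flags) > 0)
}

#' Mono-exponential T1 fit of a variable-TR series
#'
#' Nonlinear least squares of the saturation-recovery model
#' S = S0 (1 - exp(-TR / T1)). The design is flagged ill-conditioned when all
#' TRs exceed about three times the fitted T1 (the curve is flat there and T1
#' is weakly identified).
#'
#' @param series A [relax_series()] with mode `"T1_vtr"`.
#' @return A `relax_fit` object (use [generics::tidy()] / [generics::glance()]).
#' @export
fit_t1_vtr <- function(series) {
  stop_if_not_(inherits(series, "relax_series") && series$mode == "T1_vtr",
               "series must be a relax_series with mode T1_vtr")
  tr <- series$times_ms; s <- series$signals
  # profiled grid search: for fixed T1 the optimal S0 is linear LS, which
  # gives a robust start (and a fallback when the surface is flat)
  t1_grid <- exp(seq(log(min(tr) / 50), log(20 * max(tr)), length.out = 400))
  rss_of <- function(T1) {
    f <- 1 - exp(-tr / T1)
    S0 <- sum(s * f) / sum(f^2)
    c(S0 = S0, rss = sum((s - S0 * f)^2))
  }
  grid <- vapply(t1_grid, rss_of, numeric(2))
  kbest <- which.min(grid["rss", ])
  start <- list(S0 = unname(grid["S0", kbest]), T1 = t1_grid[kbest])
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ S0 * (1 - exp(-tr / T1)), start = start,
                      lower = c(1e-12, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  flags <- character(0)
  if (!is.null(fit)) {
    co <- coef(fit)
    resid <- stats::resid(fit)
  } else {
    if (kbest == length(t1_grid))
      abort(sprintf("T1 fit did not converge: no recovery curvature in the data (profile minimum at T1 ~ %.3g ms, RSS %.3g)",
                    t1_grid[kbest], grid["rss", kbest]))
    # flat-likelihood fallback: keep the profiled grid optimum, flagged below
    co <- c(S0 = start$S0, T1 = start$T1)
    resid <- s - start$S0 * (1 - exp(-tr / start$T1))
    flags <- c(flags, "nls_fallback_profile_grid")
  }
  if (min(tr) > 3 * co[["T1"]]) flags <- c(flags, "ill_conditioned_all_TR_gg_T1")
  new_relax_fit(series, co[["S0"]], co[["T1"]], "t1_saturation_recovery",
                resid, flags)
}

#' Mono-exponential T2 fit of a CPMG echo series
#'
#' Fits S = S0 exp(-TE / T2) by signal-weighted log-linear least squares
#' (weights S^2, correcting the log transform's heteroscedasticity), with an
#' optional nonlinear refinement.
#'
#' @param series A [relax_series()] with mode `"T2_cpmg"`.
#' @param refine Run a nonlinear refinement after the log-linear fit.
#' @return A `relax_fit` object.
#' @export
fit_t2_cpmg <- function(series, refine = FALSE) {
  stop_if_not_(inherits(series, "relax_series") && series$mode == "T2_cpmg",
               "series must be a relax_series with mode T2_cpmg")
  te <- series$times_ms; s <- series$signals
  stop_if_not_(all(s > 0), "non-positive signals cannot be log-fitted")
  fit <- lm(log(s) ~ te, weights = s^2)
  sl <- coef(fit)[["te"]]
  stop_if_not_(sl < 0, "signals do not decay with TE; T2 undefined")
  s0 <- exp(coef(fit)[["(Intercept)"]]); t2 <- -1 / sl
  if (refine) {
    nfit <- tryCatch(
      minpack.lm::nlsLM(s ~ S0 * exp(-te / T2), start = list(S0 = s0, T2 = t2)),
      error = function(e) NULL)
    if (!is.null(nfit)) {
      co <- coef(nfit)
      s0 <- co[["S0"]]; t2 <- co[["T2"]]
    }
  }
  resid <- s - s0 * exp(-te / t2)
  new_relax_fit(series, s0, t2, "t2_monoexponential", resid, character(0))
}

#' Transverse signal fraction remaining at an echo time
#'
#' exp(-TE / T2): the design rule behind choosing TE 23-25 ms for muscle with
#' T2 = 35 ms (about half the transverse signal remains).
#'
#' @param TE_ms Echo time (ms).
#' @param T2_ms Transverse relaxation time (ms), > 0.
#' @return Fraction in (0, 1].
#' @export
t2_signal_fraction <- function(TE_ms, T2_ms) {
  stop_if_not_(all(T2_ms > 0), "T2 must be > 0")
  exp(-TE_ms / T2_ms)
}

#' SNR-efficient repetition time for a given T1
#'
#' TR = 1.3 x T1 (the usual SNR-efficiency optimum for saturation-recovery
#' acquisitions), plus a suggestion rounded up to the next 50 ms (a slightly
#' longer TR costs little SNR efficiency; a shorter one costs signal).
#'
#' @param T1_ms Longitudinal relaxation time (ms), > 0.
#' @return A list: `TR_ms` (exact) and `TR_suggested_ms` (rounded to 50 ms).
#' @export
optimal_tr <- function(T1_ms) {
  stop_if_not_(all(T1_ms > 0), "T1 must be > 0")
  tr <- 1.3 * T1_ms
  list(TR_ms = tr, TR_suggested_ms = ceiling(tr / 50) * 50)
}

#' Diffusion-length parameters
#'
#' @param lambda1 Reference in vivo axial diffusivity (um2/ms).
#' @param Delta_ms Diffusion time (ms).
#' @param temp_reduction Fractional ADC decrease from scanning at room
#'   temperature (about 2% per degree C below body temperature).
#' @param fix_reduction_range Fractional ADC decrease interval attributable
#'   to fixation (neurological tissue shows 30-80%).
#' @return A `diffusion_length_params` object.
#' @export
diffusion_length_params <- function(lambda1 = 1.6, Delta_ms = 15,
                                    temp_reduction = 0.30,
                                    fix_reduction_range = c(0.30, 0.80)) {
  stop_if_not_(lambda1 > 0, "lambda1 must be > 0")
  stop_if_not_(temp_reduction >= 0 && temp_reduction < 1,
               "temp_reduction must be in [0, 1)")
  stop_if_not_(all(fix_reduction_range >= 0 & fix_reduction_range < 1),
               "fix_reduction_range must be in [0, 1)")
  structure(list(lambda1 = lambda1, Delta_ms = Delta_ms,
                 temp_reduction = temp_reduction,
                 fix_reduction_range = sort(fix_reduction_range)),
            class = "diffusion_length_params")
}

#' Expected diffusion length under reduced effective diffusivity
#'
#' Computes l_D = sqrt(D_eff Delta) with
#' D_eff = lambda1 (1 - temp_reduction)(1 - fix_reduction) at both ends of
#' the fixation-reduction interval. The in vivo reference axial diffusivity
#' of ~1.6 um2/ms with a 30% temperature and 30-80% fixation reduction at
#' Delta = 15 ms gives roughly 1.8-3.4 um, i.e. an order of magnitude below
#' typical fiber diameters. A `sqrt(2 D Delta)` one-dimensional RMS variant
#' is available via `per_axis_factor2`.
#'
#' @param params A [diffusion_length_params()].
#' @param per_axis_factor2 Use sqrt(2 D Delta) instead of sqrt(D Delta).
#' @return A tibble with `l_d_low_um` (most reduced) and `l_d_high_um`
#'   (least reduced) and the effective diffusivities.
#' @export
diffusion_length <- function(params, per_axis_factor2 = FALSE) {
  stop_if_not_(inherits(params, "diffusion_length_params"),
               "params must be diffusion_length_params")
  fac <- if (per_axis_factor2) 2 else 1
  d_eff <- params$lambda1 * (1 - params$temp_reduction) *
    (1 - rev(params$fix_reduction_range))            # [most, least] reduced
  ld <- sqrt(fac * d_eff * params$Delta_ms)
  tibble(l_d_low_um = ld[1], l_d_high_um = ld[2],
         d_eff_low = d_eff[1], d_eff_high = d_eff[2],
         Delta_ms = params$Delta_ms)
}

#' Temperature-driven ADC reduction
#'
#' `rate_per_C * delta_T_C`, capped at 1 (100%) with a flag. A ~2%/degree
#' rate over a 15 degree drop from body to room temperature gives the 30%
#' reduction used in the diffusion-length estimate.
#'
#' @param rate_per_C Fractional ADC decrease per degree C (>= 0).
#' @param delta_T_C Temperature drop (degrees C).
#' @return A list: `fraction` and `capped`.
#' @export
temperature_adc_reduction <- function(rate_per_C, delta_T_C) {
  stop_if_not_(rate_per_C >= 0, "rate must be >= 0")
  f <- rate_per_C * delta_T_C
  list(fraction = min(f, 1), capped = f > 1)
}
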