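# myodti

Simulation-based analysis of how scalar DTI metrics relate to skeletal-muscle
microstructure.

## The problem

Muscle DTI scalars — fractional anisotropy (FA), mean diffusivity (MD),
radial diffusivity (RD) — are routinely interpreted as readouts of myofiber
geometry (diameter, cross-sectional area, surface-to-volume ratio). Whether
an acquisition can actually see the sarcolemma depends on the diffusion
length

    l_D ≈ sqrt(D_eff · Δ)

relative to the fiber diameter. For fixed muscle at room temperature imaged
with a spin-echo PGSE sequence at Δ = 15 ms, temperature (~30%) and fixation
(30–80%) reductions of an in vivo axial diffusivity of 1.6 µm²/ms leave
l_D ≈ 1.8–3.4 µm against 30–70 µm fibers — so pixel-wise correlations between
co-registered DTI and histology should be negligible, and validating DTI
against histology in that regime is expected to fail for physical rather
than technical reasons.

`myodti` makes that argument executable end to end, with no external data:

* **synthetic histology** — Lloyd-relaxed power-diagram fiber packings with
  lognormal size distributions, endomysial gaps, shrinkage erosion and
  proximo-distal size gradients (`generate_fiber_packing()`,
  `generate_section_series()`);
* **morphometry** — per-fiber diameter/area/S/V with a Crofton perimeter
  estimator, per-pixel metric maps, and gap-compensating masked-mean
  down-sampling with histogram-consistency checks (`fiber_stats()`,
  `paint_morphometry_maps()`, `downsample_masked_mean()`);
* **restricted-diffusion Monte-Carlo** — permeable-membrane random walks
  with full finite-lobe PGSE phase encoding and Rician noise at measured
  SNRs (`simulate_walkers()`, `pgse_signal()`, `synthesize_dwi()`);
* **tensor fitting** — signal²-weighted linear least squares, FA/MD/RD maps,
  local-PCA (Marchenko–Pastur) denoising, SNR measurement and the
  SNR-versus-accuracy Monte-Carlo (`fit_tensor_field()`, `lpca_denoise()`,
  `snr_accuracy_simulation()`);
* **relaxometry & protocol arithmetic** — mono-exponential T1 (variable-TR)
  and T2 (CPMG) fits, TR/TE selection helpers, diffusion-length calculator
  (`fit_t1_vtr()`, `fit_t2_cpmg()`, `optimal_tr()`, `diffusion_length()`);
* **co-registration & correlation** — boundary contours, thin-plate-spline
  boundary registration, grid resampling, pooled pixel-wise Pearson
  correlations with the conventional interpretation bands
  (`extract_boundary()`, `register_boundaries()`, `pixelwise_correlation()`);
* **pipeline** — the QC/location ledger and the end-to-end synthetic
  experiment at 0.25 and/or 0.5 mm resolution (`plan_locations()`,
  `apply_qc()`, `run_experiment()`).

Tabular results come back as tibbles; fitted objects support
`generics::tidy()`/`glance()`; result objects have `ggplot2::autoplot()`
methods. Label rasters travel as 16-bit TIFF + JSON sidecars, DWI volumes as
NIfTI + FSL-style bval/bvec.

## Worked example

```r
library(myodti)

# 1. the regime argument, as numbers
diffusion_length(diffusion_length_params(
  lambda1 = 1.6, Delta_ms = 15,
  temp_reduction = 0.30, fix_reduction_range = c(0.30, 0.80)))
#> # A tibble: 1 × 5
#>   l_d_low_um l_d_high_um d_eff_low d_eff_high Delta_ms
#>        <dbl>       <dbl>     <dbl>      <dbl>    <dbl>
#> 1       1.83        3.43     0.224      0.784       15

# 2. a synthetic section and its morphometry
p <- fiber_packing_params(region_width_um = 600, region_height_um = 600,
                          mean_diameter_um = 30, diameter_cv = 0.3, seed = 7)
m <- generate_fiber_packing(p, pixel_size_um = 0.75)
st <- dplyr::filter(fiber_stats(m), !edge_flag)
c(n = nrow(st), mean_d = mean(st$equiv_diameter_um))
#>        n   mean_d
#> 365.0000  30.0630     # requested 30 µm recovered

# 3. the end-to-end experiment in the study regime (several minutes)
res <- run_experiment(experiment_config(seed = 1))
res
#> <experiment_result>
#>   0.5 mm arm: 1000 pooled voxels, max |r| = 0.099 (negligible)
```

The nine pooled correlations all land in the negligible band (|r| < 0.3;
here ≤ 0.1 over 1000 voxels), with the physically expected sign pattern —
RD slightly lower where S/V is higher — buried under noise: the executable
version of the statement that Δ = 15 ms PGSE in fixed tissue cannot resolve
myofiber size. The SNR design rules behind the protocol are reproduced by

```r
ev <- muscle_tensor_eigenvalues(lambda1 = 1.6e-3, fa = 0.25)
snr_accuracy_simulation(ev, pgse_protocol(), snr_b0 = 25, n_reps = 2000,
                        seed = 11)
#> max |bias| ≈ 4.6 %     (SNR 25 → within 5%)
# and at snr_b0 = 50: max |bias| ≈ 1.0–1.1 %  (SNR 50 → within ~1%; the FA
# term sits right at the threshold)
```

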