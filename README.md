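# ecgibench

Tools for quantifying how torso-signal processing affects epicardial
potential-based electrocardiographic imaging (ECGI), for researchers who
tune ECGI pre-processing pipelines and want the interaction between
filtering and regularization measured rather than assumed.

ECGI reconstructs heart-surface potentials from body-surface ECGs through
the linear forward relation

    y(t) = A x(t) + n(t)

where `x(t)` are epicardial node potentials, `A` is the volume-conductor
transfer matrix and `n(t)` is measurement noise (power-line interference,
broadband channel noise, baseline wander). The inversion is ill-posed and
solved here with zero-order Tikhonov regularization,

    min_x ||A x − y||² + λ² ||x||²,

with `λ` selected per time instant by the L-curve corner (analytic
filter-factor curvature in the SVD basis) and pooled by its median over
each beat. Because pre-processing changes the noise that the L-curve sees,
it changes `λ` — and with it everything downstream: electrogram amplitude
and morphology, activation maps, pacing-site localization.

The package provides, as tested building blocks:

* a synthetic torso-tank generator — concentric triangulated surfaces,
  single-site paced activation, multi-beat electrograms, and seeded noise
  in the three classes above (`generate_concentric_meshes`,
  `simulate_activation`, `simulate_epicardial_beats`,
  `generate_torso_recording`);
* a boundary-element forward model with mesh refinement and electrode row
  sampling, verified against the concentric-sphere analytic solution to
  0.05% (`build_transfer_matrix`, `refine_mesh`, `sample_electrode_rows`);
* the complete 49-variant processing bank: raw, seven high-frequency
  removal methods (moving average, Pipberger, Fourier notch,
  Savitzky–Golay, 11-tap weighted average, 30/60 Hz Butterworth low-pass),
  five baseline-drift removal methods (isoelectric reset, wavelet
  bandpass, long-frame Savitzky–Golay, cubic-spline baseline, 0.5 Hz
  high-pass), their 35 combinations, and PCA-based signal averaging
  (`enumerate_methods`, `apply_method`, `signal_average`, `as_operator`);
* the inverse solver (`tikhonov_solve`, `lcurve_lambda`, `reconstruct`);
* evaluation metrics: SNR-HF, baseline shift, amplitude differences, QRS
  correlation, min-dV/dt and spatio-temporal activation times, map
  correlation/MAE, automated pacing-site localization
  (`snr_hf`, `baseline_shift`, `activation_times_spatiotemporal`,
  `locate_pacing_site`, ...);
* a study driver emitting tidy long-format results (`run_study`,
  `summarize_report`, `write_report`).

The methods vignette (`vignettes/ecgi-signal-processing.Rmd`) documents the
models, parameter choices and known limitations.

## Worked example

Simulate a contaminated torso-tank dataset, run four processing variants
through reconstruction, and compare:

```r
library(ecgibench)

cfg <- study_config(seed = 1, variants = c("RAW", "HFR1", "BDR1", "HFR6+BDR1"))
report <- run_study(cfg)
summary <- summarize_report(report)
subset(summary, metric %in% c("snr_hf_dB", "lambda_median", "at_mae_ms", "le_mm"),
       select = c(variant, metric, mean, sd))
```

```
   variant        metric   mean     sd
      BDR1     at_mae_ms 17.873 0.1650
      HFR1     at_mae_ms 14.784 1.3918
 HFR6+BDR1     at_mae_ms 10.673 0.1079
       RAW     at_mae_ms 18.408 0.2406
      BDR1 lambda_median  0.185 0.0000
      HFR1 lambda_median  0.337 0.0727
 HFR6+BDR1 lambda_median  0.147 0.0000
       RAW lambda_median  0.388 0.0248
      BDR1         le_mm  1.655 3.7016
      HFR1         le_mm  6.622 3.7016
 HFR6+BDR1         le_mm  0.000 0.0000
       RAW         le_mm  0.000 0.0000
      BDR1     snr_hf_dB 15.042 0.0000
      HFR1     snr_hf_dB 34.918 0.0000
 HFR6+BDR1     snr_hf_dB 34.604 0.0000
       RAW     snr_hf_dB 15.042 0.0000
```

Reading the table: high-frequency removal (HFR1) lifts the torso SNR-HF
from 15 to 35 dB and improves activation-time error, but leaves the
selected regularization `λ` high because the baseline wander is untouched.
Baseline-drift removal (BDR1) halves `λ` (0.39 → 0.19) — the mechanism
through which drift removal restores electrogram amplitude — but does
nothing for the high-frequency noise that corrupts activation markers.
The combination does both: `λ` drops to 0.15, SNR-HF rises to 35 dB, and
the activation-map MAE falls from 18.4 to 10.7 ms with exact pacing-site
localization (LE 0 mm on this 9 mm-spacing mesh).

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write their
tables under `results/`:

1. `analysis/01_simulate_dataset.R` — generate and export the synthetic
   dataset (OFF meshes, Matrix Market transfer matrix, CSV recordings).
2. `analysis/02_filter_bank.R` — signal-quality metrics for all 49
   variants before reconstruction.
3. `analysis/03_reconstruction_study.R` — the full 49-variant
   reconstruction study plus a noise-free reference (about four minutes).
4. `analysis/04_trend_summary.R` — comparison tables: signal quality and
   lambda, electrogram accuracy, activation/localization, category trends.

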