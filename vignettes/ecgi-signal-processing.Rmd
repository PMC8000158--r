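---
title: "How torso-signal processing shapes epicardial ECGI reconstructions: models and methods"
author: "ecgibench"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{How torso-signal processing shapes epicardial ECGI reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecgibench)
```

## The problem

Electrocardiographic imaging (ECGI) reconstructs potentials on the outer
heart surface from body-surface ECG recordings. The forward relation is
linear: at every time instant the torso potentials are

$$ y(t) = A\,x(t) + n(t), $$

where $x(t) \in \mathbb{R}^N$ holds the epicardial node potentials,
$A \in \mathbb{R}^{M\times N}$ is the volume-conductor transfer matrix and
$n(t)$ is measurement noise (power-line interference, broadband channel
noise, baseline wander). The inverse problem — recovering $x$ from $y$ — is
severely ill-posed, so any pre-processing applied to $y$ interacts with the
regularization that stabilizes the inversion. This package implements a
complete desk-scale pipeline for quantifying that interaction: a synthetic
torso-tank data generator, a 49-variant processing bank, a boundary-element
forward model, zero-order Tikhonov inversion with L-curve parameter
selection, and electrogram/activation-map accuracy metrics.

Experimental torso-tank preparations (a perfused heart suspended in a
human-shaped electrolytic tank, with simultaneous epicardial "sock" and tank
surface recordings) are the reference setting this pipeline emulates. No
experimental data ship with the package: every input is generated by code,
which makes all downstream claims testable without downloads, at the price
of the simplifications documented below.

## The synthetic torso tank

`generate_concentric_meshes()` builds an icosphere "epicardium" (default:
subdivision 2, 162 nodes, radius 30 mm, mean inter-node spacing ~9 mm,
comparable to experimental sock electrode spacing) inside an ellipsoidal
"torso" (semi-axes 100/150/80 mm, 162 nodes, ~34 mm spacing, comparable to
tank electrode arrays). `simulate_activation()` spreads activation from a
pacing node at a fixed conduction velocity (default 0.8 mm/ms, an
epicardial-range value), using shortest paths on the mesh edge graph. The
graph metric over- or under-shoots true geodesics by a few percent at these
resolutions; that error is inherited identically by every processing
variant, so comparisons between variants are unaffected.

`beat_template()` renders the local electrogram: a biphasic RS complex
(derivative-of-a-Gaussian, so the downstroke — the intrinsic deflection —
is smooth and its time marks local activation) with an optional T wave.
Peak-to-peak amplitude is normalized to `rs_amplitude_mV` (default 10 mV).
The experimental waveforms are not parameterized anywhere, so this template
is the package's own construction. Tails below 1e-12 of the peak are
flushed to exactly zero, so a jitter-free beat train is bit-identically
periodic. `simulate_epicardial_beats()` places the template on every lead,
shifted by that lead's activation time, for `n_beats` beats (default 5 at a
700 ms cycle, 1000 Hz), and carries the ground-truth segmentation (QRS,
pre-QRS isoelectric window, QRST window).

`generate_torso_recording()` applies the forward matrix and adds three
noise classes from a seeded `noise_spec()`:

* line interference: a per-lead random-phase sinusoid at 50 or 60 Hz with
  harmonics (default amplitude 0.2 mV); independent phases reproduce the
  broken common mode seen in noisy tank recordings;
* channel noise: i.i.d. Gaussian (default SD 0.05 mV);
* baseline wander: per lead, three random-phase sinusoids drawn from a
  sub-0.5 Hz band (default amplitude 1 mV with a 1, 1/2, 1/3 taper).

Defaults were fixed once, before any evaluation, to make the noisy dataset
resemble a heavily contaminated tank recording: the resulting torso QRS is
~1.6 mV peak-to-peak against ~0.6 mV total noise, i.e. drift on the order
of the signal. Every generator output is a pure function of its arguments
including the seed. What the generator does **not** emulate: respiratory or
motion artefacts, electrode drop-out, reference-electrode behavior
(potentials are treated as already zero-referenced), intramural sources,
and torso inhomogeneities. Passing tests therefore demonstrate internal
consistency of the pipeline under controlled contamination, not performance
on experimental data.

## The forward model

`build_transfer_matrix()` assembles the homogeneous boundary-element
operator between the two closed surfaces: double-layer (solid-angle) and
single-layer coefficient blocks with vertex collocation and linear
interpolation over triangles. Per-triangle solid angles use the robust
arctangent formula; the linear partition of each triangle's angle among its
vertices uses a degree-5 quadrature rule whose total is corrected to the
exact solid angle, with subdivided quadrature for near-singular pairs and a
semi-analytic polar rule for the single-layer self terms. Diagonal terms
come from the Gauss identity (the auto-solid-angle construction), which
makes constant-potential transfer exact by construction — row sums of $A$
equal one to machine precision. The epicardial normal current is eliminated
through the single-layer block. Conductivity cancels in a
potential-to-potential transfer and is carried as metadata only.

The coupled system is nonsingular (the torso self-block alone is singular
by the Gauss identity, but the single-layer coupling removes the
deficiency), so the rank-one deflation of the torso block is applied only
if the assembled system is numerically rank-deficient, and failure beyond
deflation raises an error with a conditioning report.

Verification is against the concentric-sphere series solution for a
central-dipole surface potential with an insulated outer boundary
($\phi(b) = 3a^2b/(2a^3+b^3)\cos\theta$): 0.34% relative L2 error at
subdivision 2 and 0.05% at subdivision 3, improving monotonically with
refinement, plus exact Gauss solid-angle sums and rigid-motion invariance.

## The 49-variant processing bank

`enumerate_methods()` yields RAW, seven high-frequency removal methods
(HFR1–7), five baseline-drift removal methods (BDR1–5), all 35 HFR+BDR
compositions (HFR first, then BDR), and PCA-based signal averaging (SA).
Window lengths follow the acquisition dialect: one line cycle is 20 ms at
50 Hz, 17 ms at 60 Hz; the two-cycle window is 40/33 ms.

* **HFR1** — moving average over one line cycle. A boxcar over an odd
  number of taps cannot null the line frequency, so the window spans
  exactly `round(fs/f0)` sample intervals with half-weight endpoints
  (trapezoid); when `fs/f0` is an integer this annihilates the line
  frequency and all its harmonics exactly.
* **HFR2** — cosine-weighted (raised-cosine) average over two line cycles;
  exact line null when two full cycles fit the window.
* **HFR3** — Fourier notch: bins within ±1 Hz (configurable) of the line
  frequency and each harmonic up to Nyquist are zeroed. Hard zeroing was
  chosen over a tapered profile; broadband power outside the notch bands
  is untouched.
* **HFR4** — Savitzky–Golay, order 3, frame one line cycle.
* **HFR5** — 11-tap weighted running average. The exact production kernel
  is a toolbox default not published anywhere, so a normalized triangular
  kernel ships as the documented default and a user kernel is accepted.
* **HFR6/HFR7** — order-7 Butterworth low-pass at 30/60 Hz.
* **BDR1** — subtract each beat's pre-QRS isoelectric-window mean
  (piecewise-constant per beat, per lead).
* **BDR2** — wavelet bandpass 0.5–150 Hz, Coiflet with 4 vanishing
  moments, 20 decomposition levels requested. Implemented with an
  undecimated (stationary) transform: subband zeroing is then a single
  linear time-invariant operator, so repeated beats receive identical
  treatment — the property the downstream beat averaging relies on; a
  decimated transform leaves ~1% beat-to-beat differences from dyadic
  shift-variance. Scales whose nominal band lies inside 0.5–150 Hz are
  kept; the approximation and out-of-band details are dropped.
  Decomposition beyond the deepest sub-0.5 Hz scale only re-partitions
  coefficients that are zeroed anyway, so the depth is capped at what the
  (mirror-extended, power-of-two-padded) record supports; the output is
  identical to a literal 20-level transform.
* **BDR3** — subtract an order-3 Savitzky–Golay smooth with a 3000 ms
  frame (the smooth is the baseline estimate).
* **BDR4** — subtract a cubic interpolant through the isoelectric points
  (abscissa and value at each beat's isoelectric-window center sample).
  The interpolant uses Forsythe–Malcolm–Moler end conditions, which
  reproduce a global cubic polynomial exactly; natural end conditions
  would not. Anchors are placed strictly before QRS onset.
* **BDR5** — order-5 Butterworth high-pass at 0.5 Hz.

Every stage is zero-phase: phase shifts would displace the intrinsic
deflection and bias activation times, and zero-phase filtering keeps the
filter/reconstruction commutation exact. The Butterworth stages are
realized spectrally: the squared magnitude of the bilinear (tan-prewarped)
design — exactly what a forward–backward recursion applies — is imposed on
the mirror-extended record. A direct order-5 transfer-function recursion at
a 0.001 normalized cutoff loses about five significant digits to
cancellation, which would break the 1e-8 linearity and operator-equivalence
contracts; the spectral realization is exact, exactly linear, and has exact
unit/zero DC gain. Edge handling: moving averages reflect the record
symmetrically; Savitzky–Golay uses its least-squares partial-window edge
filters (these reproduce polynomial trends exactly at the record ends,
where reflection padding would not); Butterworth stages act on the mirror
extension. Steady-state filter properties (nulls, attenuations) are
asserted away from the edges, where any finite-record method has
transients.

`as_operator()` materializes any linear time-invariant method (all HFR;
BDR2/3/5; their combinations) as the $n \times n$ matrix $M$ with
$M s$ equal to the filtered signal. BDR1 and BDR4 depend on the beat
segmentation and SA is nonlinear, so they have no operator form and say so.
Because a purely spatial (static) regularized inverse treats every time
step independently, temporal filtering and reconstruction commute at fixed
$\lambda$ — `tikhonov_solve(A, Y %*% t(M), lam)` equals
`tikhonov_solve(A, Y, lam) %*% t(M)` to rounding — which the tests assert
as the bank's headline structural property.

`signal_average()` removes baseline wander with BDR2, takes the first
principal component across leads as a virtual lead, uses the template
beat's QRST window of that lead as the virtual template, aligns every beat
by cross-correlation (beats shifting more than half a cycle are dropped
with a message) and averages the aligned windows per lead. The extracted
window spans the whole template beat so the averaged output still carries a
pre-QRS isoelectric window for the quality metrics. A
`baseline_method = "none"` option bypasses the wavelet stage; it exists
because any real baseline filter leaves finite-record leakage that makes
"identical" filtered beats differ at the 0.1% level, and the pure averaging
machinery should be testable against exact identities.

## The inverse solver

`tikhonov_solve()` minimizes $\|Ax-y\|^2 + \lambda^2\|x\|^2$ (zero-order
Tikhonov; the regularization matrix is the identity) through the SVD of
$A$, computed once per forward matrix and reused across instants and
lambdas as filter-factor multiplications. `lcurve_lambda()` evaluates
Hansen's analytic filter-factor expressions for the residual norm, solution
norm and the signed curvature of the log-log L-curve on a grid (default 200
log-spaced points spanning $[10^{-8}, 10^{2}]$ times the largest singular
value; finite-difference curvature on coarse grids is unstable, the
analytic form is not).

Corner selection needed two robustness rules beyond "maximize the
curvature", both adopted after the raw rule demonstrably failed on this
problem class:

1. **Residual-floor gate.** A corner candidate (interior local curvature
   maximum) qualifies only if its residual is within a factor 10 of the
   smallest residual on the grid. Below a genuine corner the residual has
   plateaued at the noise level; curvature maxima whose residual is still
   falling steeply are spectral-decay features of noise-free, consistent
   data. Without the gate, noise-free reconstructions are visibly
   over-regularized (median per-lead correlation drops from 0.99 to 0.91).
2. **Rightmost corner.** Of the qualifying candidates, the one at the
   largest lambda is selected. The study's transfer matrices have
   condition numbers near $10^{11}$, and the noise-amplification branch of
   their L-curves carries spurious micro-corners — kinks at the scale of
   the smallest singular values — whose curvature can exceed the physical
   corner's. The raw maximum-curvature rule then returns near-zero lambdas
   on noise-dominated instants, occasionally collapsing the per-beat
   median and erasing the drift–regularization interaction the study
   exists to measure. The corner separating the data-fitting regime from
   the noise-amplification regime is the rightmost qualifying one.

A curvature maximum at a grid boundary never qualifies (truncation
artifact). If no corner survives, the maximum-curvature grid point is
returned with a `no_corner` flag — noise-free well-conditioned problems
land on the grid minimum, flagged, which is the correct degenerate answer.
The selection is scale-invariant in $y$. On the classic severely
ill-conditioned 1D test problem with 1% noise, the selected lambda stays
within a factor of 10 of the discrepancy-principle value.

`reconstruct()` selects a lambda per time instant of each beat's analysis
window, pools them by the median (the pooling window is the per-beat
QRST window by default, configurable to QRS; pooling over the full cycle
was evaluated and rejected — corner selection on near-flat diastolic
instants is erratic), and solves every instant of the window at the median
lambda, beat by beat.

## Evaluation metrics

All metrics follow their operational definitions: SNR-HF (after an
internal BDR1 correction: the across-lead RMS curve's QRS peak over its
RMS in a 40/34 ms pre-QRS window, in dB, ratios averaged across beats
before the log); baseline shift (mean absolute per-lead mean of the 20/17
ms isoelectric window); electrogram amplitude differences (mean per-lead
peak-to-peak; absolute, and relative to the maximum recorded peak-to-peak);
per-lead QRS Pearson correlation with its median; activation times by
minimum derivative (central difference, no pre-smoothing — smoothing is
the filters' job); a spatio-temporal activation-time variant that blends
min-dV/dt candidates with cross-correlation delay estimates between
mesh-adjacent leads through a regularized least squares (this follows a
one-sentence published description of such algorithms and is an
interpretation, not a reproduction); activation-map Pearson correlation
and mean absolute error; and automated pacing-site localization (earliest
node whose 1-ring neighbor median activates within 30 ms, ties averaged,
with the Euclidean distance to the true site as localization error).

`run_study()` drives any subset of the 49 variants through filtering,
per-beat reconstruction and evaluation into one tidy long-format table
(variant, beat, metric, value); the signal-averaged single beat is
compared against every unaveraged truth beat. Variant failures are
recorded and skipped. Aggregation is descriptive (mean, SD, median);
significance testing is out of scope.

## Problem sizes and reproducibility

The shipped configurations run the study at 162 epicardial nodes, 162
torso leads, 5 beats of 700 ms at 1000 Hz (the record must exceed the
3000 ms BDR3 frame, hence 3.5 s), with the sphere oracle at subdivision 3
(642 nodes); a full 49-variant study completes in about four minutes on
one CPU. Every random quantity flows from explicit seeds; identical
configurations produce byte-identical tables. Study outputs carry a
provenance sidecar (config hash, seed, package version).

## Known limitations

* The torso is a homogeneous ellipsoid; no lungs, no inhomogeneities, no
  realistic tank geometry. The transfer matrices are correspondingly more
  symmetric (and at matched resolution more ill-conditioned) than
  experimental ones.
* Activation propagation is a graph geodesic at constant velocity; no
  anisotropy, no intramural breakthrough patterns.
* The electrogram template is stylized; T-wave morphology and
  repolarization metrics are out of scope.
* The experimental studies' quantitative results (correlation ranges,
  localization-error distributions measured on tank data) are
  data-dependent and are not reproduced here; the package reproduces the
  qualitative trends — HFR raises SNR-HF but a pure notch leaves
  broadband noise; BDR collapses the baseline shift and the selected
  lambda, recovering electrogram amplitude; combinations improve
  activation mapping — under its own synthetic conditions.
* Reference-electrode effects and motion/respiration artefacts are not
  modelled.
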