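---
title: "A digital head phantom for quantitative susceptibility mapping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital head phantom for quantitative susceptibility mapping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmphantom)
```

## What the package simulates

Quantitative susceptibility mapping (QSM) reconstructs the volume magnetic
susceptibility chi (in ppm) of tissue from the phase of multi-echo
gradient-echo MRI. Validating a QSM pipeline on in-vivo data is circular —
there is no ground truth — so the field works with digital phantoms: a
known chi distribution is pushed through a physically faithful forward
model, the resulting complex data are processed like a real acquisition,
and the reconstruction is compared against the known truth.

`qsmphantom` implements that loop end to end:

1. **Ground-truth composition.** Each tissue class contributes a modulated
   susceptibility `chi_t(r) = chi_mean + a (R2*(r) - R2*_ref) + b (R1(r) -
   R1_ref)`, anchoring realistic texture to the relaxometry maps; the
   per-class maps are mixed by partial-volume probabilities obtained by
   smoothing each binary brain-tissue mask with a 3-D Gaussian (FWHM 1.2
   voxels). Veins and non-brain classes stay sharp. Two calibrated
   coefficient tables ship with the package (`tissueTable("model1")`,
   `"model2"`).
2. **Forward field.** The frequency shift is the k-space product of chi
   with the Lorentz-corrected dipole kernel `D(k) = 1/3 - kz^2/|k|^2`,
   computed after zero padding by a factor 2 per axis to suppress circular
   convolution, with `D(0) = 0` fixing the arbitrary field offset to zero.
   A brain-only, demeaned variant of chi (`localizeChi`) generates fields
   with "perfect" background-field correction built in.
3. **Signal model.** Complex echoes follow the steady-state spoiled
   gradient-echo equation with a seeded second-order polynomial transceiver
   phase spanning 2 pi over the brain, optional complex Gaussian noise at a
   prescribed peak SNR, and Fourier-crop downsampling that mimics a
   lower-resolution Cartesian acquisition. A TE-independent white-matter
   frequency term driven by fractional anisotropy and fiber angle can be
   added.
4. **Reference processing.** Quality-guided region-growing unwrapping of
   echo-difference phases, weighted least-squares frequency fitting, and
   background removal by the Laplacian boundary-value (LBV) method.
5. **Baselines and metrics.** Thresholded k-space division (TKD) and
   closed-form L2 inversions, and the seven-challenge-metric suite
   (`scoreReconstruction`).

A seeded synthetic head generator (`generateHead`) supplies labels,
parameter maps and ROI masks with brain-like geometry, so every stage is
testable without downloading acquired data.

## The synthetic head: what it emulates, and what it does not

The generator builds concentric ellipsoidal layers (scalp fat, muscle,
skull, CSF, cortical gray matter, white matter), six deep-gray nuclei and a
thalamus as spheres, vein cylinders (radius 1–3 voxels), one calcification
sphere and air cavities carved into the lower head layers. R1 and R2* are
per-class means with Gaussian-random-field texture (correlation length 3
voxels, clipped at ±3 SD). The 7 T class means follow literature values
(white matter T1 1100 ms, cortical gray matter T1 1900 ms and T2* 33 ms,
globus pallidus T2* 14 ms, and so on).

Texture SDs are sized from the *susceptibility* side: through the Model-1
coefficients each term contributes about ±0.06 ppm (3 SD) of chi texture —
the amplitude seen in measured QSM — capped at a few percent of the rate
itself for weakly coupled tissues. Sizing the rate SDs directly (e.g. 5–8%
of the mean everywhere) would be realistic for the rates but, multiplied by
the larger coefficients of the dentate or substantia nigra, would produce
chi texture several times stronger than measured maps show.

The *brain mask* is the intracranial mask including CSF, as in the QSM
challenge masks. This matters for background removal: with a cortex-tight
mask the LBV boundary sits directly on strong cortical and venous sources,
and the harmonic component it absorbs penetrates essentially the whole of a
desk-scale brain; with the skull-tight mask the boundary values are weak
and the residual error localises at the mask edge and veins, which is the
behaviour the evaluation checks for.

What the phantom does **not** emulate: cortical folding, anatomical atlas
geometry, coil sensitivities, flow, respiration-induced field
fluctuations, distortion, chemical shift or exchange. Passing tests on
this phantom therefore demonstrates the correctness of the forward and
processing chain and the qualitative error phenomenology — not performance
on anatomically realistic data.

## Numerical choices and degenerate cases

- **Cross-class evaluation of the modulation.** The partial-volume mix
  evaluates each class's chi map at voxels dominated by *other* classes.
  Where those voxels hold rates from a very different compartment — most
  extremely the signal-free calcification, whose R2* is an order of
  magnitude above any brain tissue — a literal evaluation explodes (tens
  of negative ppm at calcification voxels). `composeHeadChi` therefore
  clamps each class's rate maps to the range observed over its own binary
  label before evaluating the modulation; inside the class this is a
  no-op, so the pure operations (`tissueChiMap`, linearity properties)
  are unaffected.
- **R2* reliability blend.** Near strong field gradients apparent R2* is
  inflated, so the composition blends towards an `a = 0` variant where a
  low-pass-filtered (Gaussian, FWHM 5 mm) field-gradient magnitude exceeds
  0.08 ppm/mm, reaching the `a = 0` model fully at 0.3 ppm/mm, linearly in
  between. Both thresholds are configurable.
- **Dipole kernel.** Continuous-k form on the FFT frequency lattice
  (rather than a discretised spatial dipole); an 8^3 brute-force circular
  convolution oracle pins the equivalence to 1e-10 ppm.
- **Shim simulation.** Least-squares fit of Legendre-polynomial products of
  total order up to 3 over the mask, coordinates normalised per axis. Note
  that this basis contains non-harmonic terms; subtracting them cannot be
  undone by harmonic background removal, so shimming is kept off in runs
  whose purpose is to isolate LBV behaviour.
- **Gibbs suppression.** Per axis, each line is shifted by 21 candidate
  subvoxel offsets via FFT phase ramps; a sample is replaced (by the
  shifted value interpolated back to the voxel centre) only where the best
  shift reduces a one-sided local total variation (window 3 samples,
  computed separately left and right of the voxel so an edge jump does not
  pollute its own neighbourhood) to below 30% of the unshifted value.
  The decisive-drop gate distinguishes genuine ringing — where alignment
  with an oscillation null almost eliminates local variation — from
  texture, leaves smooth data bit-identical, and makes the operation
  idempotent. It is applied only to the downsampled ground-truth chi;
  simulated complex data keep their ringing, which is part of the physics.
- **Echo combination weights.** Per-voxel weighted least squares of
  unwrapped phase against TE with weights `TE^2 |S|^2` (phase noise
  variance scales as `1/|S|^2`; the TE^2 factor emphasises late echoes
  where susceptibility phase dominates). Voxels with zero magnitude get
  frequency 0 and an `Inf` residual flag.
- **Unwrapping.** Echo *differences* are unwrapped spatially (smaller
  excursions per step), then integrated across echoes. The region-growing
  order is by quality = inverse local phase-gradient variance, seeded at
  the highest-magnitude voxel, which keeps 2-pi failures confined to the
  signal-free calcification's immediate surrounding.
- **LBV.** 7-point finite-difference Laplacian solved by successive
  over-relaxation (omega = 2 / (1 + sin(pi / max(grid)))) on the mask
  eroded by one voxel, Dirichlet values from the measured field on the
  boundary shell; convergence at relative residual 1e-6, hard failure
  after 10^4 sweeps. The returned local field is demeaned over the solved
  mask.
- **Inversions.** TKD uses the sign-preserving amplitude clamp
  `F/(t sign D)` inside the cone (the most common published variant); the
  closed-form L2 penalty is the discrete first-difference gradient
  spectrum `|G(k)|^2 = sum 4 sin^2(pi k_a / n_a)`. Both are linear
  operators, verified as such.
- **Microstructure term.** The first-order fiber-orientation frequency
  shift is `dw = dw_chi - (5 (sin^2 theta - 2/3) FA/0.59 + 3)` rad/s at
  7 T, applied only inside the white-matter mask; because the grouping of
  this empirical expression is not settled, an alternative left-to-right
  grouping is selectable via an argument. The term is stored
  TE-independent, before multiplication by TE in the signal phase.

## Evaluation metrics

`scoreReconstruction` computes the seven challenge scores: demeaned
normalised RMSE over the brain; detrended RMSE over tissue (GM+WM), a
1-voxel-dilated vein mask, and the six-nuclei deep-gray mask (the fitted
recon-vs-truth slope is divided out first, so proportionality errors land
only in the slope metric); the absolute deviation from 1 of the
through-origin regression of the six nuclei means on their prescribed
means; the SD of the difference map over a hollow rectangular prism around
the calcification (inner boundary 2 voxels outside its bounding box, outer
boundary 6 voxels further, clipped to the brain); and the volumetric
susceptibility moment integrated over the calcification region. RMSE-type
scores are multiplied by 100. The detrending fit includes an intercept but
compensates only the slope; the slope metric uses through-origin
regression; both choices are configurable.

## Problem sizes and the study conditions

The default generator grid is 128^3 voxels at 1 mm; the end-to-end checks
run the challenge protocol (TR 50 ms, TE 4/12/20/28 ms, flip 15 deg) at
native resolution and after 2x Fourier-crop downsampling, and the
regularisation sweeps use 11 TKD thresholds in [0.005, 2/3] and 13 L2
weights in [1e-6, 1]. Protocols P1 (TR 16 ms, five echoes to 36 ms, flip
23 deg) and P2 (TR 40 ms, echoes 4/12 ms, flip 8 deg) ship as presets. The
noiseless, native-resolution, local-field loop recovers the ground-truth
frequency map to rounding error (~1e-15 ppm) outside the signal-free
calcification — the structural sanity check everything else builds on.

## Known limitations

- The head geometry is ellipsoid-based; morphology-driven reconstruction
  methods would receive unrealistically smooth priors.
- The LBV solver is a plain SOR iteration; very large grids would warrant
  a multigrid or FFT-preconditioned solver.
- The synthetic fiber-angle field is spatially smooth but not derived from
  a tractography-consistent orientation model.
- Only TKD and closed-form L2 baselines are included, by design — they
  exist to exercise the metric suite, not to represent the state of the
  art.
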