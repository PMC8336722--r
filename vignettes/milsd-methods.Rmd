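---
title: "Learned spectral decoloring with multiple illumination: models, assumptions and numerical choices"
author: "milsd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned spectral decoloring with multiple illumination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Multispectral optoacoustic imaging measures, per pixel and wavelength, a
signal

S(x, λ) = Γ(x) · A(x) · ϕ(x, μa(·, λ), μs′(·, λ)) · μa(x, λ),

with the Grüneisen parameter Γ, a wavelength-independent acoustic
reconstruction factor A, the light fluence ϕ and the absorption coefficient
μa.  Oxygen saturation sO2 = c(HbO2)/(c(HbO2) + c(Hb)) determines the shape
of μa(x, ·), so it could in principle be read off the spectrum — but the
fluence ϕ depends on the absorption and scattering of the *whole* volume and
is itself strongly wavelength dependent.  This "spectral coloring" distorts
every measured spectrum and is the dominant error source of naive spectral
fitting (linear unmixing, LU).

Learned spectral decoloring (LSD) side-steps explicit fluence inversion: a
regressor is trained on simulated absorbed-energy spectra
H(x, λ) = ϕ·μa, each normalized by its L1 norm and labeled with the true
saturation.  Because Γ(x)·A(x) is wavelength independent, the L1-normalized
signal spectrum equals the L1-normalized absorbed-energy spectrum, so a model
trained on simulated Ĥ applies to measured Ŝ.  Multiple-illumination LSD
(MI-LSD) concatenates the normalized spectra observed under several
illumination positions; the systematic variation of the coloring with the
illumination site is exactly the extra information that helps disambiguate
the local saturation.

The package implements the full in-silico pipeline: chromophore models,
randomized digital tube phantoms, a 2D optical forward engine, feature
extraction, RF/NN regressors, an LU baseline and error reporting.  Saturation
means either sO2 (hemoglobin family) or the relative copper fraction
rCu = cr(CuSO4)/(cr(CuSO4) + cr(NiSO4)) of the copper/nickel sulfate
phantom system that mimics blood: CuSO4 at its whole-blood-equivalent
concentration (0.25 M) plays HbO2, NiSO4 (2.2 M) plays Hb, and the sulfate
volume fraction SVF plays the blood volume fraction.

## Spectral models

* **Hemoglobin** endmembers are computed from a bundled literature molar
  extinction table at whole-blood total hemoglobin 150 g/l (molar mass
  64,500 g/mol) and shipped as plain-text μa tables over 660–1000 nm;
  requests outside that range raise an error naming the range, inside it
  linear interpolation is used (the acquisition grid of 20 nm is coarse
  against the tables).
* **Sulfates** are bundled as a documented parametric approximation (a
  Gaussian NIR band peaking at 810 nm for CuSO4, a decaying exponential
  plus offset for NiSO4, coefficients fixed in the source).  Published
  figures of these spectra are only plots, not tables; all pipeline math is
  invariant to the exact endmember values, and `bundledEndmembers()` accepts
  user tables as overrides.  The two curves cross once in-band, mirroring
  the hemoglobin isosbestic point near 800 nm.
* **Water** comes from a bundled literature table; the background absorption
  of a voxel is water plus the background mixture at its volume fraction,
  while tube interiors are the undiluted mixture (volume fraction 1, no
  added water term — the convention under which the endmember tables are
  referenced against a water blank).
* **Scattering** follows the generic tissue power law
  μs′(λ) = μs,500′ · [f_ray (λ/500)⁻⁴ + (1 − f_ray)(λ/500)^(−b_mie)] with
  defaults μs,500′ = 42.4 cm⁻¹, f_ray = 0.62, b_mie = 1.0 — the nominal
  1.5 % fat-emulsion background (≈15 cm⁻¹ at 750 nm).  `fitScatteringModel()`
  fits these parameters to (λ, μs′) tuples by Levenberg–Marquardt least
  squares; tube interiors contain no scattering agent, so tube μs′ = 0.

## The synthetic training distribution

`samplerConfig()` defines the randomized training volumes: two sets of
tubes with per-set counts from the discrete uniform U{3, 9}, tube and
background saturation from U(0, 1), background volume fraction from
U(0, 3) %, tube radius 0.4 mm.  These marginals are the study conditions and
are not tuning knobs.

Quantities the protocol leaves open were fixed once, by the imaging
configuration they emulate:

* **Placement bounds.** Tube centers are drawn laterally within ±9.6 mm
  (the 19.2 mm field of view of the 64-channel linear probe) and at depths
  2–10 mm, bracketing the depths the physical phantoms probe (≈3–8 mm).
  Training tubes far outside the illuminated, imaged region would contribute
  samples no measurement can produce, and at desk-scale volume counts they
  dominate the training budget without improving the estimator where it is
  evaluated.
* **Volume extent.** 32 mm laterally — wide enough to contain the four-beam
  illumination array (centers ±12 mm, 7 mm FWHM) — and 14 mm deep, several
  diffusion lengths below the deepest tube.
* **Voxel pitch.** 0.3 mm, a compromise between tube discretization
  (≈5–6 voxels per 0.4 mm-radius tube section) and the cost of the
  per-wavelength diffusion solves.  Halving the pitch doubled the sample
  count but left held-out errors unchanged, so the coarser grid is used.
* **Two tube sets** differ only in sampling bookkeeping, not in depth range;
  the protocol's tube-count distribution (6–18 tubes per volume) is what
  matters downstream.
* Overlapping tubes are rejection-resampled (up to 100 attempts per tube —
  physical tubes cannot intersect), and every volume is reproducible
  bit-for-bit from its seed.

## The 2D forward engine

The desk-scale engine works in the 2D imaging plane: transversal tubes are
disks, illumination beams are Gaussian profiles (7 mm FWHM, centers 8 mm
apart) entering the top surface normally.  Two backends share the interface:

* **Finite-difference diffusion** (default for dataset generation): solves
  [∇·(D∇) − μa]ϕ = −q with harmonic-mean face diffusivities, Robin
  (extrapolated-boundary) conditions, and the source placed one transport
  mean free path under the surface.  Because the transport is genuinely
  two-dimensional, the dimensionally consistent coefficient
  D = 1/(2(μa + μs′)) and extrapolation length (π/4)·l_tr are used; with the
  familiar 3D forms (1/3, 0.71·l_tr) the solver disagrees with the package's
  own 2D Monte Carlo by up to ±17 % over 5–14 mm, with the 2D forms by ≤4 %.
  One sparse Cholesky factorization per (volume, wavelength) serves all four
  illumination positions; the symbolic analysis is cached across solves.
* **Voxel Monte Carlo** (validation backend, compiled): exponential free
  paths against μs = μs′/(1 − g) (default anisotropy g = 0.9, matched
  refractive index), 2D Henyey–Greenstein scattering, continuous absorption
  weighting with a track-length fluence estimator (exact Beer–Lambert
  within a voxel), and deterministic termination of packets below a weight
  of 10⁻⁶.  The dropped weight is tracked, so
  deposited + escaped + dropped = launched holds to round-off and the
  termination bias is bounded by 10⁻⁶ of the delivered energy.  The RNG is
  a seeded xoroshiro128+ with Box–Muller normals, so results are identical
  across platforms and runs.

Validation ties the backends together: Monte Carlo reproduces Beer–Lambert
exactly in scattering-free media, both backends match the 2D semi-infinite
diffusion Green's function (modified Bessel K0 with an image source) within
10–15 % at 5–15 mm from the source, and they agree within 15 % at tube
locations of heterogeneous phantoms.  Diffusion-limit Monte Carlo checks run
with g = 0 at the same μs′ (the 2D similarity relation), which is an order
of magnitude faster than g = 0.9 at identical diffusive behavior.

The 18 mm gel-pad standoff can be included as a water layer for Monte Carlo
transport, but the desk-scale default launches at the phantom surface: the
collimated beams cross the clear pad essentially unchanged, and a
non-scattering layer has no meaningful diffusion approximation (D → ∞), so
including it would break backend interchangeability.

## Features, estimators, baseline

One sample per tube voxel.  MI-LSD normalizes each of the four illumination
spectra separately (inter-illumination amplitude ratios are discarded — the
per-spectrum convention; a joint-normalization alternative exists behind a
flag and is off by default) and concatenates them in illumination order:
width 64 on the default 16-wavelength grid.  LSD averages the four spectra
first and then normalizes: width 16.  The averaged-illumination LSD input is
also what the LU baseline receives, so single-spectrum methods see the same
delivered energy as MI-LSD and no method has an SNR advantage.  Mirror
augmentation appends every MI-LSD training sample with the illumination
order reversed — the scene distribution is left-right symmetric, so this is
an exact symmetry of the training distribution and doubles the sample count.
Voxels with an all-zero spectrum in any illumination are dropped and
counted.

* **Random forest**: 100 trees, maximum depth 30, and otherwise the
  reference regression-forest defaults — all features considered at every
  split and terminal nodes down to a single sample.  (Generic
  square-root-mtry defaults are a classification convention; with 64
  strongly correlated spectral features they cost ≈1.5 pp of held-out
  median error.)  Training and prediction are single-threaded and
  deterministic given the seed.
* **Feedforward network**: four hidden layers of twice the input width
  (32 for LSD, 128 for MI-LSD), leaky-ReLU activations, linear output
  clipped to [0, 1] at prediction.  Unstated training details were fixed by
  convention: mean squared error loss, plain SGD without momentum, He
  initialization, epochs counted from 0 in the learning-rate schedule
  lr(e) = 10⁻² · 0.9^(e/2), batch size 10⁵ capped at the dataset size,
  dropout 0 (the configuration that works; a dropout probability is exposed
  for comparison).
* **Linear unmixing**: nonnegative least squares of the normalized spectrum
  against the two endmembers, solved exactly in closed form for the
  two-endmember case; the saturation estimate is c1/(c1 + c0), clipped to
  [0, 1], and the degenerate all-zero case is flagged as NA rather than
  silently 0.  Nonnegativity is physically required and makes the ratio
  well defined.

## Error reporting

Errors are (estimate − truth) in percentage points.  Summaries report mean,
Q1, median Q2, Q3, IQR = Q3 − Q1 and the 90th percentile P90 for signed and
absolute errors; quantiles use linear interpolation between order statistics
(the most common convention — the reference protocol does not state one).
ROI threshold segmentation selects exactly ⌈fraction · N⌉ brightest pixels
of the mean signal (15 % for compact transversal ROIs, 50 % for elongated
longitudinal ones) with a deterministic row-major tie-break.

## The desk-scale reproduction experiment

`runExperiment()` generates 300 training and 100 held-out test volumes
(diffusion backend), trains RF MI-LSD and RF LSD, and evaluates them and LU
on all tube voxels of the test volumes — about 40,000 training samples after
mirror augmentation and 13,000 test samples, in roughly 7–8 minutes on one
CPU.  Every stage derives its RNG stream from (master seed, stage, volume),
so a rerun from the manifest reproduces the summaries exactly.  The
experiment repeats identically with hemoglobin endmembers for the sO2 analog.

What passing at desk scale does and does not show: the full-scale study
trains on 4000 volumes of 3D GPU Monte Carlo (10⁸ photon packets per map);
at 1/13 of the volume count, a 2D plane, and a deterministic forward model,
estimator variance is visibly higher — in particular MI-LSD's 64-dimensional
features need more scene diversity than LSD's 16, so at 300 volumes RF LSD
typically lands under 3 pp median absolute error while RF MI-LSD sits
slightly above it (≈3.5 pp), whereas both are equivalent at full scale.  The
qualitative conclusions the tests do establish: decoloring estimators beat
linear unmixing by a wide margin under identical conditions, features are
exactly invariant to Γ·A, and the learned mapping transfers across endmember
families.  What the synthetic data do not emulate: acoustic reconstruction
artifacts, laser noise, the Grüneisen difference between the two sulfate
solutions, melanin or other skin chromophores, and out-of-plane structure.

## Out-of-distribution scenes

`runOodExperiment()` builds longitudinal ("layout C") scenes — tubes running
along the imaging plane, rasterized as bands — from models trained on
transversal-only data, mirroring the study's OOD test.  The expected
degradation is reported, not asserted: it is an empirical observation, not a
contract.

## Known limitations

* 2D transport exaggerates shadowing (light cannot flow around a disk the
  way it flows around a cylinder), which makes deep, shadowed tubes harder
  than in 3D.
* The diffusion surrogate is inaccurate inside non-scattering tube
  interiors (it is a surrogate there, validated only to the 15 %
  cross-backend band).
* The sulfate endmembers are an approximation; users with measured tables
  should pass them through the override hook.
* No acoustic forward model, no noise model: estimator rankings at desk
  scale reflect clean spectra.
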