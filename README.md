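# milsd — learned spectral decoloring for quantitative optoacoustic oximetry

Estimating blood oxygen saturation (sO2) from multispectral optoacoustic
(photoacoustic) images is confounded by *spectral coloring*: the light
fluence reaching a vessel is itself wavelength dependent, so the measured
spectrum of a vessel is a distorted version of its absorption spectrum, and
a direct spectral fit (linear unmixing, LU) is biased. This package
implements **learned spectral decoloring with multiple illumination
(MI-LSD)**: regressors trained on simulated, spectrally colored,
L1-normalized absorbed-energy spectra — concatenated across several
illumination positions — that map a measured spectrum stack directly to
saturation.

The measured signal at position *x* and wavelength *λ* factorizes as

    S(x, λ) = Γ(x) · A(x) · ϕ(x, μa, μs′; λ) · μa(x, λ)

with the Grüneisen parameter Γ and the acoustic-reconstruction factor A
both wavelength independent. L1-normalizing each spectrum cancels Γ·A, so
normalized signal spectra equal normalized absorbed-energy spectra
Ĥ(λ) = ϕ·μa / ‖ϕ·μa‖₁ — which is what the models are trained on. Saturation
is either sO2 = c(HbO2)/(c(HbO2)+c(Hb)) with hemoglobin endmembers, or the
relative copper fraction rCu = cr(CuSO4)/(cr(CuSO4)+cr(NiSO4)) of a
copper/nickel sulfate phantom system whose spectra mimic HbO2/Hb at
whole-blood concentrations.

For whom: researchers in quantitative photoacoustics who want a
self-contained, desk-scale testbed of the MI-LSD pipeline — phantom
sampling, optical forward simulation, feature construction, estimators,
and error reporting — with every stage reproducible from a seed.

## What is inside

- **Spectral models** — bundled hemoglobin/water literature tables, a
  documented parametric sulfate model (user tables can override), the
  saturation/volume-fraction mixture algebra, and the power-law reduced
  scattering model with a least-squares fitter.
- **Digital phantoms** — a randomized training-volume sampler (two tube
  sets with counts U{3,9}, saturations U(0,1), background volume fraction
  U(0,3)%, tube radius 0.4 mm) and deterministic layouts A/B/C, rasterized
  to per-wavelength voxel optical-property maps.
- **Forward engine (2D)** — a finite-difference diffusion surrogate
  (deterministic, default) and a compiled voxel Monte Carlo backend
  (Henyey–Greenstein scattering, track-length estimator, exact energy
  bookkeeping), producing absorbed-energy stacks H(x, λ, i) for 16
  wavelengths × 4 illumination positions.
- **Decoloring** — per-illumination L1 normalization, MI stacking, mirror
  augmentation, random forest (100 trees, depth 30) and feedforward NN
  (4 hidden layers, 2× input width, leaky ReLU) regressors, and an exact
  nonnegative LU baseline.
- **Evaluation** — ROI threshold segmentation, error statistics
  (mean/Q1/Q2/Q3/IQR/P90, in percentage points), report tables, and an
  out-of-distribution (longitudinal-tube) evaluation.

## Worked example

```r
library(milsd)

# a random tube phantom from the training distribution
ph <- sampleTrainingVolume(samplerConfig(), seed = 5)
ph
#> VoxelPhantom (sulfate): 47 x 107 voxels @ 0.3 mm, 16 wavelengths, 9 tubes

# simulate its multi-illumination multispectral absorbed-energy stack
st <- simulateStack(ph)         # diffusion backend, 16 x 4 = 64 maps
samples <- extractSamples(st, "milsd", augmentMirror = TRUE)
samples
#> SpectraSet (milsd): 92 samples x 64 features (16 wavelengths x 4 blocks), 0 dropped

# the full desk-scale experiment: 300 training / 100 test volumes
res <- runExperiment(experimentConfig(family = "sulfate", seed = 42))
res$table[, c("model", "mode", "abs_q2", "abs_q3", "abs_p90")]
#>   model  mode    abs_q2    abs_q3   abs_p90
#> 1    rf milsd  3.437828  6.363583  9.881713
#> 2    rf   lsd  2.923728  5.325419  8.636657
#> 3    lu       29.522143 43.587923 57.403759
```

The columns are medians, third quartiles and 90th percentiles of the
absolute saturation estimation error on all tube voxels of the held-out
test volumes, in percentage points: the learned decoloring estimators are
roughly an order of magnitude more accurate than linear unmixing under
identical conditions (LU receives the same mean-illumination spectrum, so
no method has an energy advantage). With hemoglobin endmembers
(`family = "hemoglobin"`) the same protocol yields ≈2 pp for both RF
estimators.

A thin command-line front end over the same functions is provided at
`inst/cli/milsd.R` (verbs: `phantom`, `layout`, `simulate`, `train`,
`predict`, `evaluate`, `reproduce-insilico`).

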