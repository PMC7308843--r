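---
title: "Methods: hyperspectral chemometrics for strawberry quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral chemometrics for strawberry quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Soluble solid content (SSC, %), pH and vitamin C (VC, g kg⁻¹) are the
standard quality parameters of strawberries; their reference assays
(refractometry, pH electrode, spectrophotometric ascorbic-acid assay) are
destructive. `berryhsi` implements a non-destructive alternative: a
visible/near-infrared hyperspectral reflectance image of the intact fruit is
calibrated, segmented and reduced to spectral, color and textural features,
from which multivariate regression predicts the three parameters and renders
their spatial distribution per pixel.

The package is organised as a pipeline of testable stages, each exposed as a
plain function, and a set of numbered analysis scripts (`analysis/01` …
`05`) that drive a complete simulated storage experiment.

# The synthetic storage experiment

No public dataset accompanies the problem, so the package carries a
generator whose output has the statistical structure every downstream stage
assumes. The default experiment mirrors the standard design: 120 fruit in
5 storage-time groups of 24, one scene per fruit.

**Latent quality.** Each fruit has a triple (SSC, pH, VC) drawn from
truncated normals inside the observed ranges (SSC 3.4–8.4 %, pH 2.68–3.33,
VC 0.4745–0.8421 g kg⁻¹). Group means drift with storage time — SSC rises
then falls (carbohydrate hydrolysis vs. respiration), pH and VC decline —
with offsets of roughly half the half-range, so the groups span the full
observed ranges. Within-group spread is 0.25 half-ranges.

**Forward model.** Reflectance over the native grid (280 bands, 374 nm
start, 2.31 nm step) is a logistic baseline ramp (dark below 500 nm, a
0.6–0.65 plateau at 750–950 nm) minus Gaussian-in-wavelength absorption
components: fixed dips at 680 nm (chlorophyll), 750 nm and 960 nm (water),
plus per-parameter components whose depths are linear in the latent z-score.
SSC deepens the 680 nm dip and raises the plateau (through a broad 850 nm
component); pH and VC lower the plateau and deepen the 750 / 960 nm dips
respectively. All spectra stay strictly inside (0, 1), and each parameter's
influence is confined to its own wavelength windows, which the tests
exploit.

**Scene rendering.** The fruit is an axis-aligned ellipse (~30 % of a
64×64 frame, a desk-scale stand-in for a 692×692 camera). Per ROI pixel the
forward-model reflectance is distorted by an affine scatter `a + b·r` with
`a ~ N(0, 0.1)`, `b ~ N(1, 0.1)` — exactly the distortion multiplicative
scatter correction removes, which makes MSC testable as an inverse
problem — plus additive N(0, 0.01) band noise. A planted left-to-right
linear SSC gradient (±0.15 half-ranges, i.e. ±0.375 % SSC across the fruit)
gives every scene per-pixel ground truth for the distribution-map stage.
Raw counts are `dark + (white − dark)·r` against constant reference frames;
the background is spectrally flat and dim in the red band. Everything is
reproducible from one integer seed.

**What the generator does not emulate:** photon/shot noise, bidirectional
reflectance and 3-D fruit geometry, specular highlights, instrument
wavelength drift, and spatial texture tied to chemistry (within-fruit pH/VC
are constant). Passing tests therefore demonstrate the correctness of the
pipeline's algorithms under the stated noise model, not instrument-grade
performance on real fruit.

# Pipeline stages and their parameters

**Calibration.** `calibrate()` applies the flat-field correction
`R = (R_raw − R_d)/(R_w − R_d)` element-wise and refuses division by zero
with the offending element named. In the noiseless limit it inverts the
generator to ≤1e−10, which the acceptance checks recompute.

**Band crop.** The 374–400 and 1000–1020 nm ends are noisy in practice;
`crop_bands()` keeps the closed interval [400, 1000] nm. On the native grid
this leaves 259 bands (the count follows from the 2.31 nm step; an
instrument with a slightly different grid would give 260).

**Segmentation.** The fruit is found by its super-red characteristic: the
score image `2R − G − B` from the band images nearest 691/531/457 nm,
thresholded by Otsu's method (the threshold is a parameter; Otsu is the
default because no fixed threshold is universally right), then reduced to
the largest 4-connected component to drop background specks. On default
synthetic scenes the mask matches the true ellipse with IoU ≥ 0.95.

**Pretreatments.** `wt_denoise()` is an orthonormal Daubechies-4 (8-tap)
periodized transform, level 3, with symmetric-reflection padding to a
dyadic-friendly length; details are soft-thresholded at the universal level
`σ̂√(2 ln n)` with `σ̂ = median|d₁|/0.6745` per row. These are declared
defaults — the wavelet family/level/rule are not dictated by the problem —
and zero-threshold reconstruction is the identity to machine precision,
which pins the filter bank's correctness. `msc()` regresses each spectrum
on a reference (`x = a + b·m`) and returns `(x − a)/b`; the reference is
the calibration-row column mean and is frozen before prediction rows are
corrected, so no information leaks across the split.

**Features.** Color: mean, population SD and signed-cube-root skew of the
691/531/457 nm ROI intensities (9 features, reflectance scale, no 8-bit
quantization). Texture, per band image: the gray level–gradient
co-occurrence matrix over 16×16 max-scaled levels of intensity and Sobel
gradient magnitude, yielding the standard 15 statistics (dominance sums,
marginal energies, means, variances, correlation, three entropies in bits,
inertia, homogeneity; 0·log 0 = 0 and zero-variance correlation defined as
0), plus a Gabor filter with envelope σ = (2, 4) px, orientation 60°, and
frequency 0.25 cycles px⁻¹ (the frequency is a declared convention — only
scale and orientation are standard in this configuration), zero-DC by
construction, summarised by mean, SD and 64-bin histogram entropy of the
response magnitude (3 features). Two bands per target (676/910, 444/842,
837/891 nm) give the 36-feature texture block. All extractors crop to the
mask's bounding box and replace background by nearest-ROI values, so
nothing outside the mask can influence a feature. The GLGCM implementation
is held equal to a brute-force joint-table oracle on hundreds of random
images.

**Variable selection.** `cars()` (competitive adaptive reweighted sampling)
runs 50 Monte-Carlo iterations: PLSR on a random 80 % row subsample of the
retained variables, weights = normalized |coefficients|, a forced top-weight
cut following the exponential schedule from all p variables down to 2, then
weighted resampling among the survivors; each retained set is scored by
5-fold RMSECV and the minimiser wins. Two implementation choices depart
from the textbook single-draw scheme, both to control the variance of the
competitive step: per-iteration weights average 10 subsample fits (one fit
with fewer rows than variables misranks true predictors often enough to
eliminate them irrecoverably), and the resampling draws 5p times so the
exponential schedule — not the draw count — governs shrinkage. With these
choices CARS retains the full support of noiseless sparse signals and
recovers ≥8 of 10 planted bands out of 200 in every seeded acceptance run.
The PLSR component count is chosen once by RMSECV (cap 15) before the loop
and held fixed; re-tuning inside every iteration would square the number of
fits for no observed benefit. `uve()` appends p noise columns of amplitude
1e−10 × the mean column SD, runs leave-one-out PLSR, computes stabilities
`mean(b)/sd(b)`, and keeps real variables whose |stability| exceeds the
0.99 quantile of the noise block; an empty selection falls back to the full
set with a warning.

**Splitting and models.** `kennard_stone_split()` applies the max-min
Euclidean rule per storage group on column z-scores (the metric space is a
declared choice), taking ⌈3/4·24⌉ = 18 calibration rows per group — 90/30
overall; ties break toward the lower sample id so the plan is row-order
invariant. `fit_plsr()` is SIMPLS with mean centring; at full rank it
equals ordinary least squares, the oracle the tests compare against.
`fit_svr()` wraps libsvm's ε-SVR (RBF) with a seeded 5-fold grid search
over C ∈ {1, 10, 100}, γ ∈ {0.1, 1, 10}/p, ε ∈ {0.01, 0.1}. `lwr_predict()`
works in a PCA compression keeping 99 % variance, takes the 30 nearest
calibration rows (capped at n), weights them by a Gaussian kernel with an
adaptive median-distance bandwidth, and solves the weighted normal
equations with a 1e−8 ridge fallback for singular neighbourhoods; with
uniform weights and all neighbours it reduces to OLS. Metrics are
`R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²` and RMSE, each set against its own mean.
Fused color/texture blocks are z-scored with calibration statistics inside
`run_experiment()` (spectral columns stay in reflectance units) so
distance- and margin-based methods treat the blocks comparably.

**Distribution maps.** `distribution_map()` predicts every masked pixel
from its own spectrum at the model's wavelengths; `render_map()` writes a
blue→red PNG with transparent background, a colorbar strip and a JSON
sidecar recording the scaling bounds. The map experiment trains a
single-latent-variable PLSR on the full MSC-corrected calibration spectra
and applies per-pixel MSC against the frozen calibration reference. The
single component is deliberate: the first PLS direction is the empirical
covariance direction — the matched filter for the target's spectral
signature — and any additional components that sharpen cross-sample
separation (distinguishing SSC from pH/VC effects on the shared plateau)
only add pixel-noise variance while contributing a constant within one
fruit. Multi-component map models amplified per-pixel noise by two orders
of magnitude in development and are the wrong tool for within-fruit
relative maps; absolute per-fruit map levels consequently carry a small
shrinkage bias, which is the accepted trade-off.

# Numerical choices and degenerate inputs

- Requested wavelengths resolve to the nearest grid band, ties toward the
  lower band.
- Quantization `round(x·(L−1)/max)`; an all-zero image maps to level 0.
- Constant images: GLGCM returns the single-cell statistics (energy 1,
  entropies 0); the Gabor kernel is exactly zero-DC so constant images give
  zero response; SVR degrades to an explicit constant predictor when the
  response has zero variance (libsvm would return an empty model).
- MSC refuses spectra whose slope against the reference is below 1e−12.
- RMSECV folds are a seeded shuffle into contiguous blocks, fixed before
  any selection loop; every randomized routine takes an explicit seed and
  the full 27-cell experiment matrix reproduces byte-identically.

# Problem sizes

The bundled experiments use 64×64×280 scenes, 120 samples, CARS with 50
iterations × 10 subsample fits, and 50-case recovery suites; a full test
run and the acceptance script each finish in a few minutes on one core.
These sizes are the package's chosen compromise between fidelity to the
reference design (kept exactly: 120/5/24, 3:1 split, 259-band window) and
quick iteration.

# Known limitations

- The generator's simplifications listed above; in particular, texture
  features carry no chemical signal in the synthetic world, so fusion
  experiments exercise plumbing and bookkeeping, not texture's predictive
  value.
- UVE's leave-one-out ensemble is O(n) PLSR fits per call; for much larger
  n a grouped jackknife would be the natural extension.
- Distribution maps inherit the map model's shrinkage bias and are meant
  for relative within-fruit patterns; calibrated absolute maps would need a
  pixel-level noise model in training.
- ENVI support covers the package's own BSQ/double layout plus wavelength
  metadata, not the full ENVI header zoo.
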