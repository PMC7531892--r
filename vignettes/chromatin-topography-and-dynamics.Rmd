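---
title: "Chromatin topography classification and nuclear dynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin topography classification and nuclear dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromatopo)
```

This vignette documents the models implemented in `chromatopo`, the
assumptions behind them, the tunable parameters with their units and
defaults, what the synthetic generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical results beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## 1. The imaging model and the intensity-class picture

Super-resolved DNA counterstain volumes (structured-illumination microscopy,
~110–130 nm lateral and ~320 nm axial resolution) show chromatin organised
as chains of compact domains (CDs, bulk dimensions roughly 200–300 nm)
surrounded by a DNA-depleted interchromatin compartment (IC). The package
treats voxel intensity as a proxy for local chromatin density and divides
the nuclear signal into `n_classes = 7` ordered classes: class 1 is the
non-detectable signal (IC, including nucleoli, which carry no chromatin
signal and serve as an internal control), classes 2–3 the decondensed CD
surface (perichromatin), classes 4–7 increasingly dense CD interior, with
the top classes corresponding to constitutive heterochromatin such as
chromocenters. The number of bins is itself a convention — any fixed
discretisation with a dedicated "non-detectable" lowest class supports the
same downstream statistics — so `n_classes` is configurable.

### Nuclear mask

`segment_nucleus()` smooths (Gaussian, `smooth_sigma = 1` voxel), applies an
Otsu threshold, then a morphological closing with `close_radius = 2`
voxels, fills interior holes in 3D, and keeps the largest connected
component. The closing is needed because the thresholded chromatin signal
is a reticular chain: the IC gaps between chain branches belong to the
nucleus but fall below threshold. Radius 2 was fixed by a volume-neutrality
argument — with dilation at Euclidean distance ≤ r and erosion at > r, the
digital-ball asymmetry cancels at r = 2, so closing does not bias the
volume of smooth convex masks (the test suite checks a synthetic ellipsoid
to 5%). Large dark inclusions that connect to the outside through IC
channels (nucleoli in sparse nuclei) are not recovered by any closing; they
are recovered when fully enclosed by chromatin.

### Intensity calibration

DNA-dye incorporation and acquisition settings vary between micrographs, so
absolute intensities are not comparable. `calibrate_intensity()` subtracts
the modal intensity of the voxels *outside* the nuclear mask — the largest
and most stable population in the field — and clips at zero. The mode is
taken from a 256-bin histogram over the outside-intensity range (a binned
mode is robust to the near-continuous values of reconstructed data). This
anchors the lower end of the dynamic range; the upper end remains relative
per micrograph, which is why all downstream statistics are ratios, ranks,
or within-cell comparisons.

### Classification

`classify_chromatin()` fits a 7-component Gaussian mixture
(`mclust`, unequal variances) to the calibrated in-mask intensities
(subsampled to `max_fit_voxels = 30000` for speed; the subsample and the
mixture initialisation are seeded, making the stage deterministic), orders
components by mean, assigns voxels by maximum posterior, and then applies
iterated conditional modes (ICM) with a 6-neighbourhood Potts penalty
(`icm_beta = 0.7`, 3 sweeps, `icm_beta = 0` disables). The spatial step
encodes the expectation that chromatin classes form coherent regions rather
than salt-and-pepper noise; ICM over a Potts prior is the simplest
deterministic realisation of that idea. On (near-)discrete data the EM fit
degenerates (zero within-class variance); the implementation then falls
back to seeded k-means with quantile-initialised centres, which is the
exact classifier in that limit. Ties between components resolve to the
lower class for determinism. Classification after calibration is invariant
to affine intensity rescaling of the raw data, which the tests assert.

### Surfaces and morphometry

* `extract_ic_surface()` defines the IC interface as the chromatin-side
  boundary: class ≥ 2 voxels sharing a **face** with a class-1 voxel. Face
  adjacency keeps the shell one voxel thick and consistent with the
  face-counting area estimator; with this definition the shell of a digital
  sphere holds about E[max|n|]·4πr²/a voxels (orientation factor ≈ 0.83),
  which is what the tests check. A 26-neighbourhood definition would
  produce a ~30% thicker shell.
* `surface_to_volume()` counts boundary faces between class 1 and classes
  2–7, each weighted by its physical face area (anisotropic voxels are
  handled exactly). Face counting is exact for axis-aligned shapes but
  overestimates smooth surfaces by the classic factor 3/2;
  `method = "corrected"` multiplies by 2/3, which is asymptotically exact
  for isotropically oriented surfaces. The default reports raw face area.
* `measure_cd_widths()` splits the chromatin mask by a watershed on the
  interior (anisotropy-aware) distance transform and reports per-domain
  width = 2·max(EDT) + one mean voxel — the half-voxel term corrects for
  the distance transform measuring to background voxel *centres*, half a
  voxel beyond the true boundary. The watershed merge tolerance
  (`tolerance_nm = 20`, half a lateral voxel at typical sampling) absorbs
  discretisation maxima of the EDT without merging genuinely distinct
  domains. Because chain neighbours may genuinely interpenetrate, recovered
  mean widths on dense chains sit a few percent above the generating
  diameter; the acceptance criterion (recovery of the 250 nm generator mean
  within 15%) is evaluated on moderately dense chains where domains remain
  separable.
* `compartment_masks()` builds A/B-compartment proxies: B = perinuclear rim
  (nuclear voxels within `rim_thickness` nm of the boundary) ∪ chromocenter
  components (classes 6–7 components above `chromocenter_min_um3 = 0.05`;
  the size rule is a package convention, exposed in the configuration), A =
  the remainder.

## 2. Foci mapping

`detect_foci()` thresholds the marker channel with Otsu computed over
in-mask intensities only (outside-cell voxels would bias the threshold),
zeroes sub-threshold voxels, and splits touching spots with a 3D watershed.
The watershed is authored in the package (`watershed3d()`): ordered
flooding with 26-connectivity and a peak-to-saddle merge tolerance
(`tolerance = 0.1` of the in-mask dynamic range). Spot centroids are
intensity-weighted centres of mass in physical nm. Sub-voxel accuracy is
better than a quarter voxel on isolated Gaussian spots, and recall and
precision exceed 95% for spots separated by ≥ 4σ at peak SNR ≥ 10 (both
tested).

`filter_mcnr()` removes foci whose centroid voxel falls below the
reconstruction-quality cutoff (MCNR < 5); the boundary case retains
MCNR = 5 exactly, and every removal is counted so focus numbers are
conserved through the pipeline.

`class_enrichment()` compares observed per-class focus fractions with the
analytic expectation under uniform placement (the class volume fraction).
Empty classes report `NA` rather than −∞; an optional +0.5 pseudocount per
class is available. A Monte-Carlo baseline is intentionally not the
default: for a fixed class map the uniform expectation is exactly the
volume fraction.

`surface_distances()` uses the anisotropic Euclidean distance transform to
the surface voxel set; the sign convention (needed because markers sit on
both sides of the interface) is negative when the centroid voxel is class 1
(IC side), positive in chromatin.

`colocalize()` reports Pearson correlation over in-mask voxels and Manders
M1/M2 with Otsu thresholds; zero-variance channels yield an `NA` sentinel.

## 3. Flow correlation (direction-field analysis)

`preprocess_series()` performs bleach correction by rank-based histogram
matching to the first frame, and rigid alignment by phase correlation.

`estimate_flow()` is a gradient-based (Horn–Schunck) estimator with a
global quadratic smoothness penalty (`smoothness = 0.01` of the squared
dynamic range) in a coarse-to-fine pyramid for displacements beyond a
pixel. The regularisation weight trades noise robustness against
over-smoothing of the flow; because smoothing inflates the apparent
direction correlation length, round-trip tests through the estimator check
*flatness* of ρ_c across time lags rather than its absolute value, while
absolute recovery is tested on the direction fields themselves.

`spatial_autocorrelation()` implements the Wiener–Khinchin route:
mean-subtraction, zero padding to twice the field (finite-field, not
periodic, correlation), FFT, division by the per-lag overlap count, and
normalisation to r(0) = 1. Two design points deviate deliberately from the
bare textbook formula:

* **Direction is circular.** Correlating raw angles depends on the branch
  cut at ±π. The default encodes the direction field as the complex unit
  field e^{iθ} and takes the real part of the Hermitian autocorrelation,
  which is invariant under a global rotation of all vectors (tested); the
  literal scalar-angle mode is available for comparison
  (`direction_mode = "angle"`).
* **Normalisation.** Division by the squared mean is degenerate for
  zero-mean fields; variance normalisation (r(0) = 1) is used instead.

`fit_whittle_matern()` fits (ρ_c, ν) by bounded Levenberg–Marquardt on log
parameters with multiple smoothness starts, with the analytic limit
r(0) = 1. By default the fit is truncated at the first lag where the curve
drops below 1/e (at least 8 bins): the near-origin shape determines both
parameters, while the tail of a single-realization estimate carries
correlated finite-field noise that otherwise biases ν upward. Recovery of
ρ_c and ν on 256² synthetic fields is assessed as the mean over 10 seeds
(single-field estimates at ρ_c = 10 px scatter by ±20% because the field
holds only ~650 independent correlation patches).

`dfcc_pipeline()` assembles the per-time-lag table: flow for every frame
pair at each lag, direction autocorrelation, Matérn fit, parameters
averaged over accessible pairs. Defaults mirror the live-imaging protocol
the analyses assume: 41 nm pixels, 2 s interval, 20-frame window.

## 4. Per-pixel MSD model selection

`reconstruct_trajectories()` integrates the flow forward with bilinear
interpolation; trajectories leaving the field are clamped and flagged
(clamped trajectories plateau and would otherwise masquerade as anomalous
diffusion — consumers should discard flagged pixels near the border).
`compute_msd()` is the time-averaged MSD. Lags are capped at half the
series and at `msd_max_lag = 15` frames: long-lag time averages are noisy
and the model-discriminating information concentrates at short lags.

`fit_msd_models()` fits all five forms with bounds D, v, o ≥ 0, α ∈ (0, 2];
the offset o is part of every model (it absorbs the localisation-noise
floor 4σ_loc²). The anomalous exponent is initialised from the log–log
slope of the first lags, and each richer model is additionally started from
its nested restriction, so nested models never fit worse than their
restrictions (asserted up to optimiser tolerance). Two numerical details
matter: starting values are floored at a small fraction of the data scale,
because the Levenberg–Marquardt finite-difference step is relative to the
parameter and a start at ~0 freezes it; and the offset start includes the
τ→0 extrapolation of the curve.

`select_model()` is the Bayesian comparison. The bins of a time-averaged
MSD curve are strongly correlated — a single trajectory's curve deviates
from its expectation in a smooth, realization-specific way — so an
information criterion on raw residuals systematically prefers the
anomalous-exponent models, which absorb that wiggle. The default
`"evidence"` criterion therefore scores each candidate by generalized least
squares under the covariance of the time-averaged MSD: the relative
covariance of 2D Brownian motion (estimated once by a seeded Monte-Carlo of
1500 unit trajectories and cached per curve length) scaled by a smooth
model-free reference curve shared by all candidates, plus a conservative
Occam penalty of 2·log(n) per parameter standing in for the
parameter-volume factor of the model evidence. Plain BIC/AIC on raw
residuals remain available. Ties resolve to the simpler model, so exact
noise-free data select the most parsimonious generating model.

`hid_pipeline()` chains flow → trajectories → MSD → fits → selection per
pixel and returns categorical and parameter maps (D in µm²/s, v in µm/s;
doubling the pixel size doubles recovered v and quadruples D, which is
tested).

## 5. The synthetic generator: what it emulates, and what it does not

`nucleus_spec()` defaults define the study conditions: 96×96×48 voxels at
40×40×80 nm (a cropped 3D-SIM field), CD diameters 250 ± 30 nm, 60 chains
of 16 CDs (chromatin ≈ one third of the nuclear volume, so the chain is
dense enough that the closing recovers a contiguous territory), 80 nm
linkers, two 500 nm chromocenters, one 800 nm nucleolus, PSF FWHM
120/320 nm converted to σ by FWHM/(2√(2 ln 2)), and additive Gaussian read
noise. CD centres follow smoothed random walks inside the nuclear ellipsoid
with step = mean diameter — a curvilinear-chain topology without a polymer
simulation. Ground-truth classes populate all seven bins (IC and nucleoli
1; linkers and outer shells 2; inner shells 3; cores 4–5; chromocenter rim
and core 6–7) with a linear intensity ladder between background and peak.

The motion generator synthesises direction fields with exact Matérn
spectra (S(k) ∝ (ρ_c⁻² + |k|²)^−(ν+1), spectral method, O(N log N)),
scales them by `theta_sd = 0.5` rad, and adds a uniformly random global
direction offset per frame transition: the offset is invisible to the
rotation-invariant correlation but makes per-pixel step directions
isotropic over time, so diffusive pixels perform genuine unbiased 2D random
walks (Rayleigh step magnitudes with per-axis sd √(2DΔt)). Drift pixels
keep a temporally persistent direction field and step v·Δt. Frames are
backward-warped textures (filtered Gaussian noise) — a stand-in for real
chromatin texture, whose true spatial statistics the generator does not
claim to match. For trajectory-level studies, `simulate_trajectories()`
produces exact fractional-Brownian (Cholesky), drift, and
localisation-noise components for all five MSD models.

Known gaps between the generator and real data, and hence the limits of
what green tests show: no photon (Poisson) noise — reconstructed SIM data
are not Poisson, but real noise is neither purely Gaussian nor stationary;
no reconstruction artifacts (the MCNR map is painted per spot rather than
derived from stripe contrast); intensity plateaus are sharper than real
chromatin density gradients, so the reported 7-class accuracy on phantoms
is an upper bound; the flow texture and the Eulerian advection model ignore
out-of-plane motion; and domain geometry is spherical, whereas real CDs are
irregular.

## 6. Problem sizes and determinism

The test and acceptance workloads are sized for a single core: 256² fields
and 10 seeds for Matérn recovery; 100 trajectories of 100 frames per
motion class for model selection (per-pixel MSD classification needs longer
series than the 20-frame flow-correlation window — with 2 s intervals a
100-frame acquisition is a normal live-imaging session); 64×64×32 phantoms
for segmentation accuracy; 10⁴ foci for enrichment convergence. Every
random stage takes an explicit seed, the pipeline seed fans out to
sub-stage seeds, and third-party RNG consumers (the mixture initialisation
subsample) are wrapped, so `run_pipeline()` is bit-reproducible; the RNG
state of the caller is always restored.

## 7. Known limitations

* The intensity classifier approximates the original spatially-regularised
  mixture idea with GMM + ICM; it is not a reimplementation of any specific
  hidden-Markov code, and class boundaries on shallow gradients depend on
  `icm_beta`.
* The CD-width estimator (2·max interior EDT per watershed domain) is this
  package's operational definition of "domain dimension"; other definitions
  (Feret diameters, fitted ellipsoids) would differ on irregular domains.
* Face-counting surface area is exact only for axis-aligned interfaces; the
  2/3-corrected mode is exact only asymptotically for smooth surfaces.
* The flow estimator's smoothness penalty biases the absolute direction
  correlation length upward; comparisons across conditions (same estimator
  settings) are meaningful, absolute values carry the estimator in them.
* MSD model selection near decision boundaries (e.g. α → 1, v → 0)
  necessarily degrades; the reported recovery rates hold for well-separated
  generating models at SNR ≥ 10.
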