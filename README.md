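# chromatopo

Quantitative analysis of nuclear organisation from 3D super-resolution
microscopy, and of chromatin dynamics from live-cell time series — with a
synthetic-nucleus generator that gives every stage a ground truth to be
tested against.

## The scientific problem

Super-resolved DNA counterstain images of mammalian nuclei resolve chromatin
into a reticular chain of ~200–300 nm chromatin domains (CDs) separated by a
DNA-depleted interchromatin compartment (IC). Two families of questions
follow:

1. **Topography** — where does a given marker (a histone modification,
   nascent RNA, an architectural protein, imaged as diffraction-limited
   foci) sit relative to this landscape? This package segments the nucleus,
   calibrates intensities against the extranuclear background mode, and
   divides the chromatin signal into *k* = 7 ordered intensity classes:
   class 1 is the IC, classes 2–3 the perichromatin (CD surface), classes
   4–7 the CD interior up to constitutive heterochromatin. Marker foci are
   detected (Otsu threshold + true-3D watershed), quality-filtered on a
   modulation contrast-to-noise ratio (MCNR ≥ 5) map, and summarised as a
   per-class enrichment profile, log2[(n_c/N)/(V_c/V_nuc)], and as signed
   Euclidean distances to the IC/chromatin interface.

2. **Dynamics** — how does chromatin move? From a 2D live series (41 nm
   pixels, 2 s interval) the package estimates dense optical flow, computes
   the spatial autocorrelation of the flow direction field by FFT
   (Wiener–Khinchin), and fits the Whittle–Matérn correlation model
   r(ρ) = 2^(1−ν)/Γ(ν) · (ρ/ρ_c)^ν · K_ν(ρ/ρ_c)
   for the correlation length ρ_c and smoothness ν. Per pixel, trajectories
   are reconstructed by integrating the flow, the time-averaged MSD is
   computed, and five motion models are compared by Bayesian model
   selection:

   | model | MSD(τ) |
   |-------|--------|
   | D     | 4Dτ + o |
   | DA    | 4Dτ^α + o |
   | V     | v²τ² + o |
   | DV    | 4Dτ + v²τ² + o |
   | DAV   | 4Dτ^α + v²τ² + o |

   yielding maps of the selected model and of D (µm²/s), α, and v (µm/s).

Because raw microscope volumes are rarely shareable, the package includes a
first-class synthetic generator: an ellipsoidal nucleus with curvilinear CD
chains, chromocenters and signal-free nucleoli imaged through an
anisotropic Gaussian PSF; class-biased marker foci; and flow-advected frame
series whose direction fields have known Matérn correlation and whose
per-pixel dynamics follow a chosen MSD model. Every analysis stage has a
parameter-recovery test against this ground truth.

## Worked example

```r
library(chromatopo)

sim  <- generate_nucleus(nucleus_spec(seed = 1))     # synthetic 3D-SIM nucleus
mask <- segment_nucleus(sim$dna)
cal  <- calibrate_intensity(sim$dna, mask)
cm   <- classify_chromatin(cal, mask, seed = 1)
cm
#> chromatin_classmap: 96 x 96 x 48 voxels, 7 classes
#>   class volumes (um^3): 1.64, 1.04, 1.21, 1.07, 0.879, 3.29, 0.116

surface_to_volume(cm)$ratio_um                        # 7.60 (um^-1)
measure_cd_widths(cm, min_class = 3L)$mean_nm         # 387 nm

placed <- place_foci(sim$classmap,
                     foci_spec(n_foci = 400,
                               class_weights = c(0.5, 2, 2, 1, 1, 0.5, 0.5),
                               seed = 2),
                     sim$dna$voxel_size)
det <- detect_foci(placed$marker, mask)
det <- filter_mcnr(det, placed$mcnr_map, cutoff = 5)
det <- assign_classes(det, cm)
det <- det[det$class >= 1, ]; class(det) <- c("foci_set", "data.frame")
class_enrichment(det, cm, pseudocount = TRUE)$log2_fc
#> -1.40 -0.63  0.30  0.88  0.26  0.06 -2.11
```

The profile reads directly: this marker is depleted from the IC (class 1,
log2 FC −1.4) and from dense heterochromatin (class 7, −2.1), and enriched
in the CD body (classes 3–5), as expected for foci placed with affinity for
the domain shell. Signed interface distances summarise the same geometry in
nanometres:

```r
det <- surface_distances(det, extract_ic_surface(cm), cm)
attr(det, "mean_nm")
#> 50  (positive = chromatin side of the IC interface; n = 168 foci)
```

Dynamics, on a generated series with known correlation length:

```r
g   <- generate_flow_series(motion_spec(field_shape = c(64, 64), rho_c = 10,
                                        nu = 1, model = "D", n_frames = 20))
tab <- dfcc_pipeline(g$frames, max_lag_frames = 3)   # rho_c, nu per time lag
maps <- hid_pipeline(g$flow)                          # per-pixel model + D maps
```

A command-line front end with subcommands `simulate`, `topography`, `foci`,
`dfcc`, `hid`, `run-all` is installed at `inst/scripts/chromatopo-cli.R`.

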