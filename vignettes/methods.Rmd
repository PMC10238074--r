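---
title: "Models and methods behind retlesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retlesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

retlesion is a hardware-free implementation of the computational side of an
image-guided retinal laser-lesioning platform for the mouse eye: a combined
OCT/SLO instrument in which a 532 nm photocoagulation laser is steered by
galvanometers under OCT guidance, lesions are planned on en face OCT
projections, lesion formation is read out as increased OCT scattering and as
tdTomato red-to-green fluorescence photoconversion on SLO, and lesion volumes
are segmented automatically from OCT B-scans. Because the package is
hardware-free, every stage is driven by a synthetic murine-retina phantom
that emulates the statistical structure of the real data and carries exact
ground truth. This vignette documents the models, the defaults and why they
were chosen, the numerical decisions, and what the synthetic benchmarks do
and do not establish.

## The phantom: what it emulates

`phantom_params()` fixes the study conditions. The acquisition geometry
follows the emulated protocol: OCT volumes sampled over a 500 × 500 A-scan
raster with 5 repeated B-scans per position (so a full acquisition is
2500 frames), and two-channel SLO stacks of 200 frames at 7.8 Hz over a
1024 × 1024 px field. Tests and benchmarks retain the protocol-defining
quantities (repeat counts, frame counts, rates, split sizes, overlap
fractions) and scale down only the pixel dimensions of individual B-scans
and SLO frames (typically 64–128 px per axis); those benchmark sizes are the
package's own choice of problem size and are stated with each test.

The axial model is a sum of Gaussian reflectivity bands, one per retinal
layer (NFL through RPE), with the RPE as the dominant scatterer — the
melanin-rich RPE is the primary absorber of the 532 nm laser and the
brightest outer-retina feature on OCT. Layer depths and thicknesses
(`default_layers()`) are plausible for an adult mouse retina (~155 µm from
NFL to RPE); reflectivities are relative linear intensities. A smooth
quadratic bow (default 40 µm peak) models residual retinal curvature;
vessels are dark curvilinear structures that attenuate everything beneath
them (shadowing), which is precisely the failure mode that motivates the
robust surface-detection design below.

Speckle is modelled per voxel as multiplicative Gamma noise with unit mean
and configurable contrast (default 0.35), independent across repeated
B-scans — this is what makes repeat averaging reduce noise by √r — plus a
small additive noise floor. The phantom does *not* model physical optics
(PSF, aberrations, confocal sectioning), intra-frame raster shear, or
speckle decorrelation physics; a passing pipeline therefore demonstrates
algorithmic correctness on data with the right first- and second-order
structure, not robustness to every optical artifact of a real instrument.

### Lesion dose–response

No quantitative dose–response is published for this preparation, so the
phantom's lesion model is the package's own, built to reproduce the
qualitative phenomenology: lesions anchor at the RPE and propagate inward
with dose; severity accumulates over repeated pulses; low-severity lesions
(single 6 mW, 200 ms pulse) are confined to the outer retina.

With delivered energy $E$ (mJ) accumulated over all pulses at a site, the
scattering gain applied to the volume is

$$ g(x,y,z) = 1 + \Delta_{max}\,(1 - e^{-E/E_0})\;
   G_{lat}(x,y;\sigma_{eff})\; A(z;E), $$

where $G_{lat}$ is a Gaussian lateral footprint, and $A$ is 1 on the axial
interval from the RPE up to `axial_growth_um_per_mj` × $E$ above it, clipped
at the OPL. The ground-truth lesion mask is the set of voxels with
$g > 1.2$ (fixed threshold). Defaults: $E_0 = 2.5$ mJ (so one 1.2 mJ pulse
reaches ~38 % of saturation and four reach ~85 %, matching "increasing
contrast with each pulse, nearly saturated after four"), $\Delta_{max} =
1.5$, axial growth 15 µm/mJ (one pulse stays within the outer ~20 µm; four
pulses span OPL→RPE), lateral σ = 20 µm against a 50 µm nominal spot.

The lateral scale grows with dose, $\sigma_{eff} = \sigma\,(1 + \gamma
E/E_0)$ with $\gamma = 0.25$: observed lesion extent grows strongly with
delivered energy across a 4–20 mJ titration, and with a fixed σ the
thresholded footprint would grow only logarithmically once the axial extent
clips at the OPL, flattening the dose–size curve the titration benchmark is
meant to exercise. Setting $\gamma = 0$ recovers a fixed footprint.

### Photoconversion and motion

tdTomato photoconversion follows a single-hit saturation model: the
converted fraction at a lesion centre is $\phi = 1 - e^{-\kappa E}$ with
$\kappa = 0.45$ mJ⁻¹, chosen so that one low-severity pulse is clearly
visible ($\phi \approx 0.4$) and four pulses approach complete conversion
($\phi \approx 0.89$), consistent with "almost complete photoconversion in
the high-severity patches". The red channel carries tdTomato × (1 − φ); the
green channel carries a GFP baseline plus converted signal with a
`leak_gain` detection factor (cross-talk between PMT channels is not
quantified anywhere, so this stays a free parameter, default 0.9). Partial
return of tdTomato contrast at 7 days is a single `recovery_fraction`
(default 0.35) applied on request; no kinetics are claimed.

Respiratory motion is a Poisson event process at 1.5 Hz (the observed
~1–2 Hz), each event displacing the frame it falls in by a 40 µm lateral
excursion in a random direction (within the observed <50 µm) with a
defocus-like intensity dip standing in for the dominant axial component
(<200 µm); events last tens of milliseconds, shorter than the 128 ms frame
period, so whole-frame rigid displacement is used rather than intra-frame
shear — a deliberate simplification.

## Calibration and co-registration

Lesion aiming is calibrated by fitting a 2D tensor-product polynomial from
galvanometer command voltages to observed lesion positions on a grid target;
the SLO→OCT unwarp uses the same machinery on detected grid landmarks. The
polynomial degree is not dictated by anything in the protocol, so it is a
config parameter (default 3, enough for smooth scan distortion without
overfitting a ~50-point grid; the synthetic tests use the degree of the
generating distortion). Fitting uses a shifted/scaled basis on [−1,1]² for
conditioning; exported coefficients are converted to the natural monomial
basis so the JSON is self-describing. Underdetermined systems and collinear
grids are hard errors, not warnings.

Inversion (retinal target → voltage) is damped Newton with the analytic
polynomial Jacobian, seeded from the best point of a 50 × 50 forward-sampled
grid over the domain; the default tolerance is 0.1 µm, two orders below the
~5 µm optical spot. Targets whose nearest forward-sampled image point is
further than three grid cells are rejected as outside the calibrated image
(resampling via `apply_unwarp()` instead marks such pixels `NaN` and reports
coverage, so downstream averaging can mask them).

Landmark detection finds local maxima a configurable prominence above
background and refines each to an intensity-weighted centroid in a
quarter-spacing window with a 10 %-of-peak weight threshold — the window and
threshold keep rectified-noise bias below ~0.1 px at SNR 20. Matching
pre-aligns with a similarity transform fit on extreme corner points, trying
all corner subsets of size 2–4 and keeping the seed with the most
mutual-nearest-neighbour inliers (so one or two spurious extremes cannot
corrupt the alignment), refits on the inliers, and gates matches at half the
median nearest-neighbour spacing.

## OCT processing

Repeated B-scans are averaged voxelwise. The RPE is detected per A-scan as
the *deepest* local maximum of the axially median-filtered profile that
reaches 40 % of the A-scan's peak — "brightest point" rules fail under
vessel shadows, whereas the RPE remains the outermost qualifying peak — then
regularized by an iteratively reweighted quadratic surface fit (the retinal
bow is smooth at field scale) that replaces outliers beyond 5 voxels, and a
2D median filter. The OPL is the strongest local maximum in a 40–110 µm band
inner to the detected RPE; the band excludes the bright NFL. A volume in
which more than 5 % of A-scans have no peak above the noise floor is
rejected as featureless.

Flattening shifts each A-scan by an integer voxel count so the reference
surface sits at its median depth, zero-filling (never wrapping) and carrying
a validity mask plus the shift map, so it is exactly invertible on surviving
voxels. En face projections reduce the half-open slab [top, bottom) — chosen
half-open so adjacent slabs partition the volume — with a mean reducer by
default (whether the original en face views averaged or summed over depth is
not stated; the reducer is exposed). The standard inner-retina view projects
a fixed 70 µm slab ending at the OPL rather than starting at the volume top:
projecting from the top dilutes the mean with a bow-dependent amount of dark
vitreous and produces a centre-to-edge intensity gradient (a known
volume-projection artifact) that would masquerade as contrast.

## SLO processing

Frame quality control scores each frame by its phase-correlation peak
against the pixelwise median frame and rejects frames scoring below
median − 3·MAD or displaced beyond a configurable gate (default 10 px at
full resolution; scaled-down tests use the µm-equivalent). Translation
estimation is phase correlation with Hann windowing and regularized spectral
whitening (full whitening is unstable against border zero-fill and noise),
parabolic sub-pixel refinement, and a final integer-snap: when the rounded
shift explains the frame essentially as well (overlap SSD within 5 %), it is
preferred, because sub-pixel interpolation spuriously lowers noise-dominated
SSD and would otherwise micro-shift already-aligned frames. Registration is
translation-only — observed lateral motion is small and rotation-free — with
the first kept frame as reference, the same shift applied to both channels,
and an NaN-aware masked mean.

Photoconversion is quantified per pixel as the bounded index
$p = G'/(G' + R)$, with $G'$ the green signal above the pre-lesion baseline
and $R$ the post-lesion red signal. The bounded form (rather than raw
$G'/R$) is stable as $R \to 0$ at complete conversion; $p$ is exactly
invariant to any common gain on both channels, and pixels with $G' + R$
below a noise floor are `NA`. Lesion localization thresholds $p$ (default
0.5; low-severity single-pulse analyses use ~0.25, below the single-pulse
plateau of ~0.38), labels 8-connected components, and reports
intensity-weighted centroids; lesions with touching footprints merge — a
documented consequence of the connectivity definition.

## Lesion planning

"50 % spot-size overlap" is interpreted as centre pitch = 0.5 × spot
diameter, so adjacent discs overlap by half a diameter; this algebraic
reading is stated prominently because the phrase alone does not define it.
Patch plans lay a row-major raster (serpentine available by flag, row-major
by default since the original raster order is unstated) anchored at the
treatment-mask bounding box offset by one spot radius — anchoring to the
mask, not the image, makes plans translation-covariant with the mask. A site
is kept iff its full disc lies inside the treatment mask and touches no
exclusion pixel (conservative at vessel borders; `allow_partial` relaxes the
treatment-side rule but never the exclusion rule). The default retinal spot
diameter is 50 µm, a config-exposed choice: the instrument's 200 µm fiber
and relay demagnification do not pin down the retinal spot, and 50 µm is the
scale of the observed focal lesions. Schedules expand each site into its
repeat pulses with onsets spaced duration + interval, a 1 ms inter-site
settle, and voltages from Newton inversion of the calibration; energy
bookkeeping (Σ power × duration = sites × repeats × power × duration) is
exact by construction.

## Lesion segmentation

The segmenter is a compact 2D U-Net over flattened B-scans: an
encoder–decoder with 2× max-pool downsamplings, nearest-neighbour upsampling,
skip concatenations, ReLU activations, and a 1×1 sigmoid head, trained with
weighted cross-entropy plus a soft-Dice term by per-image Adam. The
convolutions, backward pass, and optimizer are implemented directly in R
(im2col as matrix products); the backward pass is verified against numerical
gradients in the test suite. Defaults are deliberately desk-scale — depth 2,
base 8 channels, whole B-scans as input (dimensions must divide by
2^depth) — and every knob (depth, width, rates, loss weights, epochs up to
the protocol's 50, threshold) is in `seg_config()`. Training is fully
seeded: two runs with the same configuration produce identical logs and
weights; the best-validation-Dice checkpoint is returned.

The data protocol mirrors the emulated study: `split_dataset()` gives the
seeded 80/20 split (32/8 at n = 40), `make_folds()` the 5- and 10-fold
cross-validation partitions, `dice()` the validation metric (empty-vs-empty
defined as 1, empty-vs-nonempty as 0 — the degenerate cases are never
defined in segmentation papers, so they are fixed here explicitly).
`make_segmentation_benchmark()` builds the standard synthetic benchmark: 60
single-B-scan volumes (96 × 64 px at 3 × 6 µm pitch), each processed through
the same averaging/flattening path as real data, with one lesion of random
dose 1.2–6 mJ (one to roughly four low-severity pulses) at a jittered
central site and ~10 % lesion-free negatives. `make_titration_series()`
reproduces the 5-level severity titration (4 × 100 ms pulses at
10–50 mW, i.e. 4–20 mJ). On these benchmarks the held-out Dice target is
0.80 and the segmented lesion volume must increase strictly with dose
(Spearman ρ = 1). Because ground truth here is exact and lesions are
high-contrast by construction, these results bound what the architecture
and training loop can do, not what they would achieve against manual
annotations of real, denoised OCT — no claim is made about the latter.

## File formats and numerical conventions

Volumes and frame stacks are multi-page 32-bit-float grayscale TIFFs with
JSON sidecars; each volume page is one B-scan (rows = depth). Float TIFFs
are read with the `tiff` package; they are written by a minimal
single-strip float32 writer inside the package, because no installed writer
emits IEEE-float sample format, and intensity data must round-trip
bit-exactly (the package's canonical intensity precision is float32). All
indices are 1-based throughout, in line with R convention; physical
coordinates are pixel-centred, $x = (i - 0.5)\,\mathrm{pitch}$, which makes
them representation-independent. Every stochastic component (phantom,
splits, training, benchmarks) takes an explicit integer seed and is
bit-reproducible given it. 3D connected components use 26-connectivity
(2D: 8-connectivity) via an offset edge list and graph components.

The package presents image containers (volumes, frame stacks, masks) as
plain S3 objects with array payloads — forcing them into data frames would
be un-idiomatic — while every naturally tabular result (landmark tables,
plans, schedules, QC reports, metrics, CV tables) is a tibble, with
`tidy()`/`glance()` methods on fitted objects and `autoplot()`/`plot_*()`
for the visual ones, so results drop directly into dplyr/ggplot2 workflows.

## Known limitations

The phantom's lesions are smooth multiplicative gain fields; real lesions
develop granular scatterers, retinal deformation from local heating, and
radial remodeling at later time points, none of which are modelled (the
single day-7 `recovery_fraction` is the only longitudinal element).
Registration is translation-only. The segmenter is desk-scale and 2D; no
claim of real-time performance is made. Calibration assumes a static
distortion field — drift over a session is out of scope.
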