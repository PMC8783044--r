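---
title: "Quantifying anchor-cell positioning, invasion and dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anchor-cell positioning, invasion and dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

During *C. elegans* vulval morphogenesis the uterine anchor cell (AC) secretes
EGF towards the vulval precursor cells, then invades through two basement
membranes (BMs) and physically connects the developing uterus to the dorsal
vulF toroid. Whether this sequence proceeds normally is read out from
fluorescence stacks through a handful of quantitative proxies:

* **Alignment.** In the mid-sagittal plane, the adherens-junction reporter
  marks the outer vulA junctions, the two punctae delimiting the AC, and the
  mid-vulF point. The alignment ratio is
  $R_A = x / y$, where $y$ is the AP distance between the vulA junctions and
  $x$ the AP distance from the AC mid-point (midpoint of the two AC-edge
  punctae) to the *nearer* vulA junction; $R_A = 0.5$ means perfect centering
  and smaller values mean displacement. $\Delta$ is the absolute AP distance
  (µm) between the AC mid-point and the mid-vulF point.
* **Invasion.** The laminin reporter draws the ventral BM as a bright ridge;
  a breach appears as an interruption. The invasive protrusion is the
  AC-reporter signal ventral of the BM; its volume is the number of
  binarized voxels times the voxel volume, and its growth rate is the
  least-squares slope of volume against time over the first 90 min after
  breaching.
* **Dynamics.** Rapid series of the actin reporter are reduced to binary AC
  silhouettes; the correlation index $C_I$ is the mean Pearson correlation of
  consecutive frames (for binary frames this is the phi coefficient). A
  dynamic, protrusive AC decorrelates quickly, so lower $C_I$ means more
  shape change.
* **Morphometry and cohorts.** vulA-junction separation over time measures
  vulval cell migration; the delay $\Delta t$ between AC fusion and dorsal
  lumen expansion is an annotated event difference; actin-ring quality is a
  categorical call summarized as a fraction of animals; vulval induction is
  the mean number of induced VPCs per animal (wild type: 3.0).

No raw image data are deposited for the study system, so every estimator in
this package is validated against a bundled synthetic-microscopy generator
with exact ground truth rather than against archived micrographs. The cohort
statistics layer additionally recomputes the few published numbers whose
inputs are printed (per-stage ring-class counts, the induction index).

## Conventions

Arrays are ordered `(z, y, x)`. The anteroposterior (AP) axis is `x` with
anterior at low `x`; the dorsoventral (DV) axis is `y` with **ventral at high
`y`**, matching laterally mounted micrographs. All physical quantities are in
micrometres; the centre of voxel `i` along an axis with pitch `d` is at
`(i - 0.5) d`. These conventions are stated once here and used everywhere.

## The synthetic scene generator

`scene_spec()` describes a two-channel scene; `build_scene()` renders its
noise-free geometry and the ground truth; `render_stack()` applies the
acquisition model; `simulate_timeseries()` adds temporal structure.

**Geometry.** Channel `ac` holds an ellipsoidal AC body (default semi-axes
1.5 × 1.2 × 1.2 µm) dorsal of a BM sheet, plus an optional invasive
protrusion: a cylindrical stalk of configurable radius crossing the BM plane
through its gap, capped by a hemisphere. The *below-BM* part of that solid —
stalk from the BM plane down plus cap — defines the true protrusion volume by
voxel-centre membership, which is what the volumetry chain estimates. The AC
reporter also concentrates into a bright ventral focus
(`ac_focus`, default 1.5× the body intensity, σ 0.25 µm, 0.5 µm dorsal of the
ventral pole); the real actin reporter shows exactly such a focus, and the
brightest-point centring used by the dynamics chain presupposes one. Channel
`bm` holds a one-voxel-thick sheet interrupted by the gap plus Gaussian
punctae (σ 0.15 µm) at the five junction-landmark positions. A scene whose
protrusion would cross an intact BM (zero-width gap, or a stalk wider than
the gap) is rejected as inconsistent.

**Acquisition model.** The scene is blurred with a separable Gaussian PSF
(default σ 0.15 µm lateral, 0.4 µm axial; kernels truncated at 4σ and
renormalized to unit sum), then passed through a camera model

$$\mathrm{counts} = g \cdot \mathrm{Poisson}(S \cdot I) +
  \mathcal{N}(0, \sigma_r^2),$$

with photon flux $S$ (default 8000 photoelectrons per unit intensity), gain
$g$ (default 2 counts/e⁻) and read noise $\sigma_r$ (default 3 counts),
quantized to 16-bit unsigned with clipping (the saturated fraction is
recorded). The count variance of a uniform patch is therefore
$g\cdot\text{mean} + \sigma_r^2$, which the test suite checks empirically.
The instruments' true gain and offset are not published, so these are free
knobs chosen once: the default exposure puts an object of unit intensity at
~16 000 counts, about a quarter of the dynamic range, a typical operating
point that leaves headroom for the brighter punctae.

**Temporal structure.** AC boundary fluctuations multiply the ellipsoid
radius by $1 + g(\hat u, t)$, where $g$ is a seven-mode low-order angular
field whose coefficients follow a stationary AR(1) process with standard
deviation `deform_amplitude` and correlation time `deform_tau` (default
60 s); amplitude 0 gives a bit-static shape. Protrusions can elongate
linearly (`protrusion$growth`, µm/min), and integer stage jitter in `(y, x)`
can be applied and is recorded in `applied_shifts`. Each fixture derives one
pseudo-random stream from its seed, split into per-frame sub-streams, so the
same spec is always bit-identical.

**Presets.** `preset_scene()` freezes the four desk-scale study conditions
used by the tests and analysis scripts: `default` (16 × 64 × 120 voxels at
0.25/0.1/0.1 µm, the full landmark scene), `protrusion` (8 × 64 × 96 at
0.5 µm z-pitch, the spacing used for protrusion time lapses), `dynamics`
(8 × 48 × 64 at 0.25 µm z-pitch, 30 s frames) and `bm-sheet` (a pure
laminin-reporter sheet with no punctae and no protrusion, for breach
studies — in the real experiments the BM and junction markers are distinct
reporters, and a junction puncta inside the gap would fill the very ridge
profile the detector scans). Whole cohorts of these scenes simulate in
seconds on one CPU, which is what makes the recovery suites routine.

## Preprocessing

**Richardson–Lucy deconvolution** uses the standard multiplicative update
with the blur and its adjoint (equal, for a symmetric Gaussian), a
denominator floor of $10^{-12}$, and a default of 20 iterations. Intensities
stay non-negative at every iteration and total intensity is conserved within
1% for objects at least 4σ from the borders. The PSF is a non-blind
separable Gaussian: the study deconvolved with instrument PSFs, but for
estimator validation on synthetic data a matched Gaussian is sufficient and
keeps the forward and inverse models consistent.

**Registration** estimates translations only, from the FFT cross-correlation
peak (integer pixels; optional sub-pixel refinement by parabolic
interpolation of the peak), accumulates consecutive shifts against frame 1,
and shifts frames back with zero fill. Worms trapped in imaging channels
translate but barely rotate, so rotation is deliberately not modelled; a
shift at or beyond half the frame is rejected as an ambiguous wrap, and a
constant frame yields a zero shift with a warning.

**Binarization.** The default mode scales an image by its maximum (or a
supplied reference) and keeps pixels at or above `level`; 0.05 is the
constant threshold used for AC reporter channels. The volumetry chain
(`measure_protrusion()`) passes `reference = 65535`: we read "a constant
threshold of 0.05" as a fraction of the 16-bit dynamic range, because that is
a genuinely constant threshold across stacks, whereas a per-stack maximum
adapts to each stack's brightest structure. Both interpretations remain
available through the `reference` argument. For dynamics series the default
is Otsu computed on the first frame and applied throughout; per-frame Otsu is
available but jitter in per-frame thresholds would itself masquerade as
shape dynamics.

**Peak-centred cropping** takes a 90 × 144 pixel window (the field-standard
crop) with the brightest pixel at `(floor(h/2)+1, floor(w/2)+1)`; ties break
towards the first maximum in row-major order and out-of-bounds regions are
zero-padded. In `correlation_series()` the window is located once, on the
first registered projection, and reused for all frames (`crop_anchor =
"first-frame"`): registration has already removed translation, so re-locating
the peak per frame only adds ±1-pixel centring jitter that deflates $C_I$ on
a static series. Per-frame re-centring remains available.

## Alignment metrics

`compute_alignment()` implements the defining ratios exactly, measuring both
$x$ and $y$ along the AP axis; when the AC mid-point is equidistant from the
two vulA junctions the anterior junction (`vulA1`) is used, a tie that does
not change the value of $x$. $R_A \in [0, 0.5]$ whenever the AC mid-point
lies between the junctions, with 0.5 attained exactly at perfect centering,
and both metrics are invariant under AP translation and reflection.

Landmarks may be supplied manually (CSV with `animal_id`, `role`, `ap_um`,
`dv_um`; manual input is authoritative, matching the semi-automated published
workflow) or detected automatically as the five brightest well-separated
local maxima of the junction channel's mid-sagittal projection with roles
assigned by AP order (`vulA1 < ac_edge_1 < vulF_mid < ac_edge_2 < vulA2`).
On rendered scenes at default SNR the automatic path recovers $\Delta$
within one lateral voxel (0.1 µm).

The dorsoventral polarity index $I_{DV}$ splits the AC mask at its
intensity-weighted DV centroid row of a summed z-projection and reports the
ventral-to-dorsal intensity ratio; rows exactly at the centroid count as
dorsal. The published protocol for this index lives in external prior work
and is not reproduced in the study itself, so this definition is a stated
stand-in, not a verified replica. Note a structural property: because the
split uses the mask's own centroid, the dorsal half always contains some
signal, so the index is finite by construction (the dorsal-zero rejection in
the code is defensive only).

## Invasion

`extract_bm_surface()` records, per AP column, the DV position of maximum
intensity within a configured DV search band of the mid-sagittally projected
laminin channel, plus that ridge intensity. `detect_breach()` marks columns
whose ridge falls below `drop_fraction` (default 0.2) of the median ridge of
the flanking intact columns, groups them into runs, and calls a breach when
the longest run spans at least `min_gap_um` (default 1 µm). The study scored
breaching by eye, so both parameters are free; at the defaults the detector
shows no false positives on 50 intact rendered sheets and detects every
≥ 2 µm gap, with extents accurate to about one column on unblurred ridges
(optics shave roughly one blurred column off each gap edge).

`protrusion_volume()` operationalizes "signal below the BM barrier" as mask
voxels ventral of the per-column ridge height. Candidates form 26-connected
components — 26-connectivity because thin diagonal stalks must survive — and
the protrusion is either the component containing a manual seed voxel
(preserving the published manual workflow) or the largest component
intersecting a detected gap (enabling unattended simulation studies). Volume
is the voxel count times `dz·dy·dx`, which makes it monotone under mask
inclusion and invariant under whole-scene AP translation. At default SNR the
full chain recovers true volumes within 15% (median over seeds); the residual
bias is a thin halo of above-threshold blur around the true boundary, a
surface effect that shrinks for larger protrusions. `protrusion_trace()`
fits the post-breach growth rate by least squares over a 90 min window
(frames every 5 min by default) and flags windows with fewer than three
frames; recovered slopes land within a few percent of truth because the halo
contributes nearly equally to every frame.

## Dynamics

The cited correlation plugin's estimator is not specified in the study, so
`frame_correlation()` adopts the standard definition: Pearson correlation
over all pixel pairs, which for binary images is the phi coefficient.
Correlation is computed after binarization, as in the published chain; a
`grayscale` option supports sensitivity analysis. Pairs whose correlation is
undefined (a constant binarized frame) are dropped and counted rather than
scored 0 — an empty frame is a segmentation failure, not evidence about
dynamics. $C_I$ is the arithmetic mean of the remaining consecutive-pair
correlations; the number of frames in a 10-min series is treated as
data-dependent rather than fixed. On simulated series $C_I$ is 1.0 within
0.02 for static shapes and decreases strictly with deformation amplitude
(means over 10 seeds: ≈ 1.00, 0.97, 0.89 at amplitudes 0, 0.05, 0.2).

## Morphometry

`vulA_distance()` returns the AP separation of the outer vulA junctions per
time point (15-min frames by default for long-term series), leaving gaps as
`NA`. `lumen_expansion_delay()` is the difference of two annotated events —
the last frame before AC fusion and the first frame of junction-ring
expansion; event detection itself is accepted as manual annotation, as in
the study, and automated detection is out of scope. `ring_occupancy()`
thresholds an annulus (reusing `binarize()` at level 0.05 of the image
maximum), assigns occupied pixels to 36 angular bins and reports the occupied
fraction, classifying `complete` (≥ 0.9), `semicircle` (0.5–0.9),
`disorganized` (> 0) or `absent` (0). These cut-offs are this package's
quantitative proxy for by-eye classes; all published counts enter the
statistics through annotated tables, so the cut-offs affect only the
automated path.

## Cohort statistics

The statistics layer calls the standard R implementations rather than
re-deriving them: Welch's t (`t.test`), Mann–Whitney U (`wilcox.test`; exact
null enumeration when both samples are ≤ 8 without ties, otherwise the
normal approximation with tie and continuity corrections), the two-sided
variance F-test (`var.test`), and the Wilson score interval
(`prop.test` without continuity correction; Clopper–Pearson by flag, since
the interval construction used by the original graphing software is not
stated). All tests are two-sided — sidedness is not stated in the source —
and significance stars follow the legend convention (0.05, 0.01, 0.001,
0.0001). Percentages are reported rounded to the nearest integer with raw
fractions retained. The test suite validates the Mann–Whitney p-value against
exhaustive enumeration of all tie-free rank patterns with both samples ≤ 6,
and the Wilson interval against its closed form.

## What the synthetic validation does and does not show

Passing the recovery suites shows that the estimators are correct and stable
under a *known* forward model: Gaussian optics, Poisson-plus-read noise,
smooth boundary deformation, rigid in-plane motion. Real micrographs add
depth-dependent aberration, autofluorescent background, neighbouring
structures in both channels, segmentation ambiguity where the AC touches the
vulF toroid, and genuinely non-rigid motion — none of which the generator
emulates. The published animal-level distributions (mean $R_A$ per genotype,
$\Delta$ spreads, $C_I$ group means, breach percentages, $\Delta t$ means)
therefore cannot be and are not reproduced here; where analysis scripts need
such cohorts they simulate clearly labelled synthetic ones. What carries
over to real data is the defining arithmetic of each metric, the documented
tie-breaks and parameter conventions, and the operating characteristics of
the detectors under the stated noise model.

## Problem sizes and numerical choices

Simulation studies run on desk-scale grids chosen as the package's standard
conditions: 16 × 64 × 120 voxels for landmark scenes, 8 × 64 × 96 for
protrusion series (19 frames), 8 × 48 × 64 for dynamics series (11 frames),
with 10 seeds per condition and 50 sheets per breach operating point.
Richardson–Lucy uses 10–15 iterations inside the simulation chains (20 as
the general default). Degenerate inputs are rejected early with named
errors: all-zero channels, empty masks, coincident junctions, non-increasing
time stamps, annuli leaving the image. Floating-point ties in the crop and
surface extraction resolve to the first candidate in scan order,
deterministically.
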