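---
title: "Methods: depth-referenced quantification of dermal staining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-referenced quantification of dermal staining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dermquant quantifies how staining is organized in skin sections of a mouse
hind-limb lymphedema model: how much of a marker is present (integrated
stained area), how deep below the epidermis it sits (the P90 depth), how
collagen is organized under polarized light (the scar index), how fast an
intradermal tracer clears (the 1–5 h ICG AUC), and how much the operated paw
swells relative to its contralateral control.  This vignette explains each
procedure, its assumptions, the defaults, and what the synthetic-data tests
do and do not establish.

## Stain segmentation

Segmentation follows a three-step recipe standard in computerized
histomorphometry:

1. the section is handled in full RGB;
2. contrast is enhanced by the *excess-color* transform, `2·C − C1 − C2`
   for the channel `C` that dominates the stain (e.g. `2R − G − B` for a
   red/brown chromogen).  Any gray pixel maps to 0 and the transform is
   invariant to adding a constant to all channels, so uniform illumination
   shifts do not move the histogram;
3. the excess map is binarized with an automatic threshold, and reviewed
   corrections can be applied afterwards as explicit add/remove rasters
   (`apply_manual_correction()`), which keeps the clean-up reproducible and
   auditable.

The automatic threshold maximizes Otsu's between-class variance.  Because
excess-color maps of 8-bit images are integers in [−510, 510], the
optimization is solved exactly on the unique-value histogram whenever the
map has at most 4096 distinct values; denser maps fall back to a 256-bin
histogram.  The returned cut is the midpoint between the two flanking
levels, and a pixel is stained only if its value is *strictly greater* than
the threshold — the tie rule is stated once and used everywhere.  A
constant map has no admissible threshold and is reported as a degenerate
histogram rather than silently binarized.

Otsu's criterion assumes the histogram is a mixture of two reasonably
populated classes.  When the stained fraction falls well below roughly half
a percent of the pixels and noise widens the background mode, the criterion
can prefer splitting the background; that failure mode is visible in the
threshold it reports (it lands inside the background mode, and the mask
balloons).  The sections this pipeline targets carry stain fractions an
order of magnitude above that regime.

## Depth profiling

All depths are measured from the basal epithelial layer, supplied as an
ordered polyline annotation.  `depth_map()` computes for every pixel the
Euclidean distance to the nearest point of the polyline (not the vertical
drop — with a curved layer the nearest-point distance is the natural
reading of "distance from the basal layer"), scaled by the pixel size.
Pixels on the epidermal side are flagged and excluded from every profile.
The convention is recorded in the object (`distance_convention`).

`depth_profile()` bins stained pixels by depth (default bin width 10 µm,
about two orders of magnitude below the P90 scale of interest, 200–1000 µm)
into stained area per bin (µm²).  The curve is absolute area, not a
tissue-normalized fraction, because the downstream summary — the
*integrated area*, the area under the depth-distribution curve — is meant
to capture the global extent of staining; a normalized variant can be
derived from the tidy output if needed.

**P90 convention.**  P90 is the depth up to which 90% of the staining is
detected.  Where the stained-pixel depths themselves are available,
`depth_profile()` computes the empirical 0.9 quantile of those depths
directly (inverse-CDF convention), which is exact and independent of the
bin grid; a point mass at 50 µm therefore has P90 = 50 µm.  Summaries that
only see a binned curve — `mean_profile()`, `split_compartments()` — use
the step inverse of the cumulative bin areas evaluated at bin start depths,
the same convention discretized to the grid.  The two agree to within one
bin width; the bin-width robustness test pins this down.

`split_compartments()` partitions a profile at the papillary/reticular
junction depth, splitting a straddling bin pro rata by width so that the
papillary and reticular integrated areas always sum exactly to the
whole-dermis area.

## Polarized-light scar index

Under crossed polarizers, picrosirius-red-stained thick (mainly type I)
collagen appears red-orange and thin (mainly type III) fibers weakly green.
`classify_birefringence()` converts to HSV and labels pixels above a
saturation floor (0.2) and value floor (0.1) as thick when the hue falls in
[0°, 50°] ∪ [340°, 360°] and thin in [70°, 160°] — the conventional
polarization bands.  Yellow hues between the windows stay unassigned
rather than being forced into a class, and the windows are validated to be
disjoint.  The scar index is the thick/thin area ratio per compartment; a
compartment with no thin-fiber signal yields an explicitly undefined index
instead of infinity.  Classification depends only on hue above the floors,
so multiplying all channels by a constant (global exposure change) leaves
it untouched.

## ICG clearance

Tracer kinetics are summarized by the trapezoidal area under the ROI mean
intensity curve between 1 h (onset of clearance) and 5 h.  With only five
sampled timepoints, fitting a parametric decay would add assumptions
without adding information, so the integral is taken directly on the
measured points, linearly interpolating the window ends if 1 or 5 h is not
itself sampled.  No background subtraction or t = 0 normalization is
applied by default; both are trivial to apply to the tidy series first if a
study design requires them.

## Morphometry

Paw swelling is `(T/Tc) × 100`, the operated-paw thickness as a percentage
of the contralateral control — unit-free and robust to calipers measuring
in different units.  Layer thickness is measured at five stations (the
conventional count of independent measurements) spread evenly along the
band's long axis, found by principal components of the mask coordinates;
at each station the extent perpendicular to that axis is reported.  Even
spacing is reproducible and unbiased along the band; optional jitter
within each stratum restores "independent placement" when desired.  Fold
changes between groups use medians, consistent with median ± IQR
reporting.

## Group statistics

* **Binwise curve comparison**: two-sided Mann–Whitney per depth bin,
  exact null when the combined n ≤ 20 without ties, normal approximation
  with tie correction otherwise.  A bin with identical values across both
  groups carries no information and gets p = 1.  No multiplicity
  correction is applied by default — the raw per-bin p is the primary
  readout — but a clearly labeled Benjamini–Hochberg column is available
  because dozens of bins are tested.
* **Kruskal–Wallis + Dunn**: the omnibus H delegates to
  `stats::kruskal.test()`; Dunn's pairwise z statistics are computed from
  the pooled mean ranks with the tie-correction term, Bonferroni-adjusted
  by default (configurable), since no installed package provides them.
* **Two-way ANOVA + Tukey**: delegated to `stats::aov()`/`stats::TukeyHSD()`;
  a fit with zero residual variance is flagged degenerate rather than
  reporting infinite F.  The test suite cross-checks the sums of squares
  against a hand decomposition on a balanced design.
* **Spearman**: rho, rho² and the two-sided p are always reported together,
  because squared coefficients are often what co-localization studies
  print and the sign would otherwise be lost.

## The synthetic-data generator

The generator exists so that every stage can be scored against exact ground
truth.  It emulates the *statistical* structure of stained skin sections,
not their appearance: a pale background, a flat or gently undulating basal
layer emitted as the polyline annotation, circular stain blobs whose
centroid depths follow a configurable law, decorative hair-follicle
profiles confined to the papillary dermis, and additive Gaussian noise
clipped to [0, 255] — the simplest noise model that stresses thresholding.
Ground truth records the rendered stained pixel count (so area conservation
is exact by construction), every centroid depth, and the empirical 0.9
depth quantile.

Choices worth knowing:

* **Pixel size.**  The default `scene_spec()` pixel size is 0.23 µm/px, a
  typical 20× whole-slide scan; synthetic scenes in the tests use 2 µm/px
  so whole sections stay a few hundred thousand pixels.  Depths scale
  linearly and areas quadratically with pixel size (tested), so nothing
  about the method depends on the raster scale.
* **Non-overlapping placement.**  For parameter-recovery cohorts, blob
  centroids are rejection-sampled to a minimum separation of two radii, so
  the rendered area is exactly `blob_count ×` disc size and the LD/control
  area ratio equals the blob-count ratio up to integer rounding.  With
  overlap allowed (the default for single dense scenes) the union area is
  the truth recorded.
* **Polarized scenes** assign thick/thin labels with exact counts
  stratified per dermal compartment, so the generated per-compartment
  thick/thin ratio is controlled exactly and is a sharp oracle for
  `scar_index()` recovery.
* **Paw cohorts** default to the four-group design (n = 8, 7, 11, 13) with
  a contralateral baseline of 2 mm — a realistic mouse hind-paw thickness;
  the baseline is a free parameter of the model and of the generator.
* **Problem sizes.**  The recovery suites use 10,000-blob sections for P90
  (where the empirical quantile is within 2% of its analytic value),
  21 sections per arm for fold-change cohorts (a typical per-condition
  image count), and 4,000 fiber pixels for polarized scenes.

What passing these tests shows: the measurement chain — segmentation,
depth mapping, binning, quantiles, ratios — recovers known parameters
without bias at realistic noise.  What it does not show: robustness to
uneven illumination, stain batch variation, folded or torn tissue,
out-of-focus regions, or annotation error in the basal polyline.  Those
belong to slide QC and are upstream of this package's contract: on real
data the basal polyline, tissue mask and junction depth are inputs traced
by the analyst.

## Degenerate inputs and tie-breaks, in one place

* constant excess map → error naming the degenerate histogram;
* value equal to the threshold → unstained;
* empty stain mask → zero profile with `p90_defined = FALSE`, not an error;
* thin-fiber area 0 → scar index undefined, not `Inf`;
* identical bin values in both groups → p = 1;
* zero residual variance in ANOVA → `degenerate = TRUE`, no Tukey table;
* control median 0 → fold change `NA` with a warning;
* add/remove correction overlapping at a pixel → error (ambiguous intent);
* Otsu ties (several cuts with equal variance) → the shallowest cut wins.

## End-to-end runs

`simulate_cohort()` writes a complete synthetic study (images, annotations,
design and ground-truth tables) and `run_pipeline()` consumes any directory
of annotated sections, writing per-section masks, tidy profile and summary
CSVs, per-group fold changes and binwise comparisons, and a JSON manifest
of every parameter — two runs with the same config and inputs are
byte-identical.  A section with a missing annotation is recorded and
skipped; the run finishes with non-zero status rather than aborting.
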