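# dermquant

Quantitative spatial analysis of dermal staining for mouse hind-limb
lymphedema studies — and for any skin histology where the question is not
just *how much* of a marker is present but *how deep* below the epidermis
it sits.

Secondary lymphedema remodels the skin: lymphatic capillaries (Lyve-1+)
that normally hug the papillary dermis infiltrate the deep reticular
dermis, matricellular proteins (periostin, tenascin-C) accumulate, collagen
matures into scar, and tracer clearance slows. dermquant implements the
computerized readouts used to quantify all of this on whole-section images:

* **Stain segmentation** — excess-color contrast enhancement
  (`2·C − C1 − C2` for the stain's dominant RGB channel) followed by
  automatic Otsu thresholding, with reproducible add/remove manual
  corrections.
* **Depth profiling** — per-pixel Euclidean distance to the basal
  epithelial layer polyline; stained area binned by depth; the **integrated
  area** (total stained area, the area under the depth-distribution curve)
  and **P90** (depth up to which 90% of staining is detected); papillary /
  reticular splits at a configurable junction depth.
* **Scar index** — thick (red-orange birefringent, mainly type I collagen)
  over thin (green, mainly type III) fiber area under polarized Sirius
  red, per dermal compartment.
* **ICG clearance** — ROI mean intensity over time and the trapezoidal
  1–5 h area under the curve.
* **Morphometry** — paw swelling as `(T/Tc) × 100`, five-site layer
  thickness, median fold changes.
* **Group statistics** — binwise Mann–Whitney curve comparison,
  Kruskal–Wallis with Dunn's post hoc, two-way ANOVA with Tukey HSD,
  Spearman correlation.
* **Synthetic sections** — a generator with exact ground truth (rendered
  stained area, every blob depth, per-compartment fiber composition), so
  the whole chain is testable without slide data.

Everything tabular moves as tibbles; fitted objects have `tidy()` /
`glance()` methods and `autoplot()` figures.

## Worked example

A synthetic control section (lymphatic-like blobs confined to the papillary
dermis), segmented and profiled:

```r
library(dermquant)

sec   <- generate_skin_section(control_scene_spec())
stain <- segment_stain(sec$image, channel = "R", marker = "Lyve-1")
stain
#> <stain_mask> Lyve-1: 40619 stained px of 330000 (threshold 106)

prof <- depth_profile(stain, depth_map(sec$image), bin_width_um = 10)
glance(prof)
#> # A tibble: 1 × 6
#>   compartment integrated_area_um2 p90_um p90_defined n_bins bin_width_um
#>   <chr>                     <dbl>  <dbl> <lgl>        <int>        <dbl>
#> 1 whole                    162476    292 TRUE            33           10
```

90% of the staining lies within 292 µm of the basal layer — inside the
225–300 µm band expected of control skin, because the generator confined
the capillaries to the papillary dermis. The integrated area (162,476 µm²)
is the total segmented stain surface; `autoplot(prof)` draws the
depth-distribution curve with P90 marked.

A polarized-light scene generated with 1.5× more thick than thin fiber
area, recovered by hue classification:

```r
pol <- generate_polarized_section(polarized_scene_spec(seed = 11), 0.6)
scar_index(classify_birefringence(pol$image), depth_map(pol$image), 350)
#> # A tibble: 2 × 5
#>   compartment thick_area_um2 thin_area_um2 scar_index defined
#>   <chr>                <dbl>         <dbl>      <dbl> <lgl>
#> 1 papillary             5492          3664       1.50 TRUE
#> 2 reticular             4048          2696       1.50 TRUE

auc_1_5(generate_icg_series(100, 0.2, noise_sd = 0)$series)
#> [1] 228.4233
normalize_paw(4.2, 3.0)   # operated paw as % of contralateral control
#> [1] 140
```

End to end: `simulate_cohort()` writes a four-group synthetic study
(images + JSON annotations + design tables) and `run_pipeline(run_config(...))`
segments and profiles every section, writing tidy CSVs, per-group fold
changes, binwise comparisons and a JSON manifest; identical configs
reproduce identical bytes. A thin command-line wrapper lives at
`inst/scripts/dermquant.R` (`simulate` and `run` subcommands).

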