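---
title: "Quantifying whole-section immunofluorescence: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-section immunofluorescence: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoquant)
```

## The problem

Injury and repair in the kidney are spatially heterogeneous: markers of
failed tubular repair (Kim1, Vcam1), proliferation (Ki67) and microvascular
density (CD31) vary patchily across the cortex and the outer stripe of the
outer medulla (OSOM). Field-of-view sampling under a microscope measures a
handful of spots; scanning whole sections and quantifying every pixel
removes the sampling step but creates new methodological obligations:

* segmentations (from any source — histogram thresholds, a random-forest
  pixel classifier, or an external deep-learning model whose masks arrive
  as files) must be *validated* against expert annotation with stated
  metrics and stated inclusion rules;
* all measurement must be restricted to the anatomically meaningful
  compartment (cortex + OSOM), supplied as a polygon outline;
* spatial covariation of two stains must be measured on defined sampling
  units rather than eyeballed from heatmaps.

histoquant implements that measurement chain end to end, with a synthetic
section generator so every stage is testable without slide data.

## Coordinate and calibration conventions

Pixels are indexed 0-based as `(row, col)`; physical coordinates are pixel
centers, `x_um = (col + 0.5) * scale`, with x along columns, y along rows,
all physical quantities in micrometres. The calibration (`scale_um_per_px`,
isotropic) is supplied by the caller — typical values are 0.5 µm/px for
slide scanners and 1.3 µm/px for a motorized epifluorescence stage — and is
never parsed from TIFF tags, because in the targeted workflow section
metadata travels in file names (a six-field underscore convention parsed by
`parse_section_metadata()`). Outlines interchange as GeoJSON polygons in
µm; point sets as CSV with `x_um,y_um` headers. Whether exported
coordinates are pixel-corner or pixel-center referenced is a convention the
upstream tools leave unstated; pixel-center is used consistently here and
pinned by tests.

## Preprocessing

`rolling_ball_subtract()` estimates slowly varying background as the
grayscale opening of the intensity surface with a *ball-shaped* (non-flat)
structuring element of height `sqrt(r^2 - d^2)` — the classic construction —
and subtracts it. The default radius is 50 px, the whole-section standard at
0.5 µm/px. Two numerical choices matter:

* Whether the reference tools use a true ball or a paraboloid approximation
  is undocumented; this implementation is an exact ball opening, pinned by a
  brute-force oracle test (radii ≤ 8 on 64×64 images, agreement at machine
  precision).
* For radii above 16 px the image is shrunk by block **minimum**, a
  proportionally smaller ball is rolled, and the background is re-expanded
  bilinearly — the standard large-radius strategy. The background is always
  clipped to ≤ input, so `input = result + background` holds exactly and
  the result is non-negative.

There is no light-background mode and no smoothing pre-pass: fluorescence
is dark-background.

## Auto-thresholding

`auto_threshold()` computes a 256-equal-width-bin histogram over
`[min, max]` of the considered pixels (8-bit semantics; 16-bit input is
binned, not truncated — scanner bit depth handling is not otherwise
specified upstream) and applies one of five classic selectors:
`default_isodata` (iterative intermeans on the histogram with the extreme
bins zeroed — the "default" of the common reference tool, distinct from
textbook IsoData), `otsu`, `triangle`, `mean` and `li`. Pixels strictly
above the threshold are positive; reference tools differ on ≥ vs >, so the
strict convention is documented and pinned by tests.

Numerical notes a maintainer should know:

* Every selector is validated bin-exactly against an independent
  brute-force criterion scan on seeded Gaussian-mixture histograms — the
  realistic case for fluorescence.
* `li` is implemented as the exact discrete minimizer of the cross-entropy
  criterion (cumulative-sum scan, smallest bin on ties). The traditional
  fixed-point iteration was tried first and on about 1 in 50 noisy mixture
  histograms it settles in a shallow neighbouring basin (criterion ~1e-6
  relative above the global minimum, a genuinely different mask); at 256
  bins the exact scan costs nothing, so it is the implementation.
* When the two intensity modes leave an empty gap in the histogram, all
  thresholds inside the gap produce identical masks and tie the selector
  criteria exactly; tie-breaks (smallest bin / first optimum) are
  deterministic and shared with the oracles.
* Per-ROI mode (`threshold_per_roi()`) treats a constant-intensity crop as
  a flagged degenerate result with an empty mask, never a batch abort.

## Pixel classifier

`train_pixel_classifier()` reproduces the shape of the default interactive
pixel classification workflow: a filter bank of Gaussian-smoothed
intensity, Laplacian of Gaussian, gradient magnitude and structure-tensor
eigenvalues at scales σ ∈ {0.7, 1.0, 1.6, 3.5, 5.0} px, feeding a bagged
ensemble of CART trees (Gini splits, √p random feature subsets). No
random-forest package ships in the supported environment, so the forest is
implemented natively; its contract is the spec's (separable-fixture
accuracy > 0.99, determinism under a fixed seed, lossless serialization),
not feature-parity with any external tool. The training seed is a required
config field (default 0).

## Nucleus detection

`detect_nuclei()` composes the standard chain for nuclear stains:
`fill_holes()` (background components not touching the border become
foreground; 8-connectivity for foreground, 4 for background),
`watershed_split()` (exact Euclidean distance transform, regional maxima as
seeds, Meyer priority flooding, 1-px watershed lines), then
`particles_to_points()` with an inclusive minimum particle area of 9 µm² —
"minimum" is read as ≥, so a 36-px particle at 0.5 µm/px (exactly 9 µm²)
is retained and a 35-px one is not.

Watershed seed suppression is the one genuinely open design area: the
reference tool's internal tolerance is undocumented. Here maxima with EDT
value < 2 px are discarded and maxima closer than 4 px are merged (single
linkage); both are parameters. Isolated blobs whose maxima are all
suppressed are rescued as their own particles rather than silently dropped.
Touching nuclei at center separation ≳ 1.8 r split cleanly with centroid
error well under 1 px; heavily overlapped pairs (≲ 1.5 r) split with
centroid shifts of 2–3 µm or merge entirely — the known 2-D overlap
limitation of this family of methods, and the reason the synthetic
generator models "touching pairs" at 1.8 r.

## Validation framework

* ROI sampling (`sample_validation_rois()`): per section, five candidate
  ROIs placed uniformly with centers inside the outline, then exactly one
  retained by a second seeded draw — so ROI choice cannot be steered by
  segmentation quality. Standard sizes: 400×400 px (membrane), 200×200 px
  (nuclear).
* Inclusion rules (`apply_inclusion_rules()`): membrane ROIs need a
  reference positive area fraction in [0.1, 0.9]; nuclear ROIs need ≥ 5
  reference nuclei. Bounds are inclusive; the sources state ranges without
  boundary semantics.
* Pixel metrics: sensitivity, specificity and Dice
  `2·TP/((TP+FP)+(TP+FN))`. Any 0/0 is returned as `NA` and named in an
  `undefined` field — degenerate ROIs must never be silently coerced to 0,
  which would bias medians downward.
* Point matching (`match_points()`): one-to-one within 5 µm
  (center-to-center, continuous µm — whether any grid rounding preceded the
  original rule is unstated). The procedure is greedy globally-nearest-first
  followed by augmenting-path repair to maximum cardinality. Pure greedy is
  provably suboptimal on adversarial configurations (two reference points
  competing for two comparator points can strand one), and the acceptance
  oracle is the exhaustive maximum bipartite matching; on realistic
  detection data — spacing well above inter-observer jitter — the repair
  is a no-op. Detection Dice is `2·|pairs|/(n_ref + n_comp)`, `NA` when
  both sets are empty.
* Validation masks are always cropped from the whole-section segmentation,
  never re-segmented per ROI.

## Quantification and spatial analysis

Area fraction, detections/mm² (boundary points count as inside),
IoU within a region (`NA` on an empty union), and structure counting as
8-connected components with an 80 µm² minimum — the enumeration rule for
"positive tubules" is not defined upstream, so the component convention is
this package's documented choice.

`density_heatmap()` is a circular mean filter (default 200 µm radius). The
denominator is the full kernel; pixels whose kernel crosses the region
boundary are flagged in a companion validity raster instead of being
renormalized, so partial values are visible rather than extrapolated.

`tile_region()` fills an outline with close-packed circles of 200 µm radius
on a hexagonal lattice (pitch 2r, rows r√3, alternate rows offset r),
anchored at the bounding-box origin by default. Containment is strict —
center inside and ≥ r from every boundary edge, holes included — because
partially contained circles would bias density denominators. Whether the
original analysis allowed boundary-overlapping circles is unstated; strict
containment is the documented choice. Correlation of paired tile densities
is sample Pearson with the t-transform p-value.

## The synthetic world

`generate_scene()` draws an ellipse-with-notch section outline, places
per-channel object centers from an inhomogeneous Poisson process whose
intensity is a log-Gaussian latent field `exp(g·Z − g²/2)` (Gaussian random
field, correlation length 300 µm by default, modulation `g = 0.8`), renders
membrane channels as annular rims (tubule radii 15–25 µm, 3 µm rim) and
nuclear channels as filled disks (radii 3–5 µm), then composes intensities
with per-class Gaussian noise, a smooth additive background (to exercise
rolling-ball) and read noise. Defaults mirror the targeted acquisition:
0.5 µm/px, densities of order 100/mm² (injury markers are patchy subsets,
far below anatomical tubule packing), 200 µm analysis radius.

Channels 1 and 2 share latent-field structure scaled so their *measured*
tile-level densities correlate at a requested ρ. The calibration is
analytic: the tile-averaged lognormal signal covariance
`C(ρ_f) = E[exp(g² ρ_f ρ(d)) − 1]` (pair-distance quadrature over the
disk) and the compound-Poisson sampling variance `E[a²]/(µ·E[a]²)` give the
field correlation ρ_f to solve for by monotone root finding; an
unreachable ρ raises a spec error. At ~900 tiles the recovered Pearson r
lands within ±0.04 of ρ across seeds (the acceptance bound is ±0.1).
Nucleus "overlap" places a fraction of nuclei as touching pairs at 1.8 r —
disks that fuse into one blob with distinct EDT maxima.

What the generator does **not** emulate: glomeruli, vessels and calyces,
staining artifacts (folds, scratches, blur), anisotropic illumination,
autofluorescence spectra, and any correlation between stain intensity and
object size. A green test therefore establishes correctness of the
measurement chain on geometrically faithful sections, not robustness to
acquisition pathology — that is what the montage QC step is for.

`degrade()` emulates re-acquisition at a coarser scale (0.5 → 1.3 µm/px)
by matched Gaussian anti-alias blur and bilinear resampling. Resolution
robustness is asserted on the measurement chain: masks carried to the
coarser grid change area fraction < 2 % and nucleus counts < 5 %.
Re-thresholding a degraded *intensity* image moves membrane area fraction
by several percent more — that measures segmentation quality at low
resolution, which belongs to the (external) segmenter, not to this
pipeline; a separate test still checks detection counts from re-thresholded
degraded images stay within 5 %.

## Known limitations

* The TIFF codec covers the pipeline's subset (uncompressed, single-channel
  grayscale, 8/16-bit unsigned and 32-bit float); anything else is rejected
  loudly rather than misread.
* Watershed separation degrades below ~4 px object radius and for overlap
  beyond ~0.3; counts, not shapes, are the supported readout there.
* The pixel classifier is a reference implementation for mask provenance
  experiments, not a performance-tuned segmenter.
* Group statistics across animals (ANOVA, mixed models) are out of scope;
  per-section summaries are exported as CSV for external tools.
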