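# histoquant

Quantitative analysis of single-channel immunofluorescence images of whole
tissue sections — built for whole-slide kidney injury studies, where markers
of failed tubular repair (Kim1, Vcam1), proliferation (Ki67) and
microvascular density (CD31) must be measured over the entire
cortex + outer stripe of the outer medulla (OSOM) rather than in
hand-picked fields of view.

The package covers the full measurement chain around a segmentation step
that can come from anywhere (its own thresholds, its own random-forest
pixel classifier, or an external deep-learning segmenter whose binary masks
arrive as TIFF files):

* **I/O & geometry** — calibrated grayscale TIFFs (µm/px supplied by the
  caller), binary masks, GeoJSON region outlines (e.g. cortex+OSOM),
  point-set CSVs, QC montages. Pixel-center coordinate convention, all
  physical quantities in µm.
* **Preprocessing** — rolling-ball background subtraction (grayscale
  opening with a true ball element, default radius 50 px), block-mean
  downsampling.
* **Segmentation backends** — 256-bin histogram auto-thresholding
  (`default_isodata`, `otsu`, `triangle`, `mean`, `li`) in whole-section or
  per-ROI mode; an ilastik-style random-forest pixel classifier on a
  Gaussian/LoG/gradient/structure-tensor filter bank.
* **Nucleus detection** — fill holes → Euclidean-distance watershed →
  particle filtering (inclusive minimum area, default 9 µm²), centroids as
  a point set.
* **Validation** — seeded ROI sampling with inclusion rules (membrane:
  positive area fraction in [0.1, 0.9]; nuclear: ≥ 5 reference nuclei),
  pixel sensitivity/specificity/Dice `2·TP/((TP+FP)+(TP+FN))`, one-to-one
  point matching within 5 µm, detection Dice
  `2·|matches|/(n_ref + n_comp)`, observer-comparison tables
  (median + IQR). Degenerate 0/0 metrics are flagged `NA`, never zeroed.
* **Quantification** — area fraction, detections/mm², IoU, structure
  counts, all restricted to a region outline.
* **Spatial heterogeneity** — circular mean-filter density heatmaps
  (200 µm radius), hexagonal close-packed circle tiling of a region
  (200 µm radius, strict containment), paired tile densities and Pearson
  correlation with p-value.
* **Synthetic sections** — a seeded generator (section-shaped outline,
  membrane rims and nuclear disks placed by a log-Gaussian Cox process,
  controllable tile-level correlation ρ between two channels, noise and
  smooth background) with full ground truth, so the entire chain is
  testable without slide data.

## Worked example

```r
library(histoquant)

# a synthetic 2 x 1.6 mm section with a membrane and a nuclear channel
spec  <- scene_spec(width_mm = 2, height_mm = 1.6, scale_um_per_px = 1,
                    rho = 0.5, seed = 42)
scene <- generate_scene(spec)
img   <- scene$images$memA
img
#> <calibrated_image> 1600 x 2000 px @ 1 um/px  channel: memA  source: synthetic_seed42
#>   intensity range [0, 271.3]

pre <- rolling_ball_subtract(img, radius_px = 50)   # background removal
thr <- auto_threshold(pre$image, method = "triangle")
sprintf("triangle threshold: %.1f", thr$result$threshold)
#> "triangle threshold: 56.9"

region <- scene$truth$region                        # cortex+OSOM mask
area_fraction(thr$mask, region)                     # 0.031
pixel_metrics(scene$truth$masks$memA, thr$mask)$dice  # 0.970

nthr <- auto_threshold(rolling_ball_subtract(scene$images$nucA, 50)$image,
                       "otsu")
pts  <- detect_nuclei(nthr$mask, min_area_um2 = 9)
density_per_mm2(pts, region)                        # 93.1 nuclei per mm^2
detection_dice(match_points(scene$truth$points$nucA, pts, radius_um = 5))
#> 0.995

tiles <- tile_region(scene$truth$outline, radius_um = 200)
tab   <- tile_densities(tiles, scene$truth$masks$memA,
                        scene$truth$masks$nucA)
pearson_correlation(tab)
#> $r 0.95   $n 6   $p_value 0.0036
```

Reading the numbers: the triangle threshold recovers the true membrane mask
at Dice 0.97 after background subtraction; nucleus detection recovers the
93 nuclei/mm² field essentially perfectly (detection Dice 0.995 at the 5 µm
matching radius); and the two channels' densities across 200 µm circle
tiles correlate strongly — though at a demo-sized section only 6 circles
fit, so the correlation is illustrative; real sections (tens of mm²) yield
hundreds of tiles.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli","histoquant.R",package="histoquant"))')
Rscript $CLI preprocess --radius-px 50 --scale-um-per-px 0.5 in.tif out.tif
Rscript $CLI threshold  --method triangle --scale-um-per-px 0.5 out.tif mask.tif
Rscript $CLI detect     --min-area-um2 9 --scale-um-per-px 0.5 mask.tif pts.csv
Rscript $CLI validate   --stain-class nuclear --radius-um 5 ref.csv pts.csv report.csv
Rscript $CLI tiles      --radius-um 200 region.geojson tiles.csv
Rscript $CLI batch      config.yaml
```

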