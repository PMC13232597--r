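# tubuleseg

Automated segmentation, classification and spatial quantification of
seminiferous tubule immunofluorescence.

## The problem

Quantifying germ and somatic cells in testicular tissue sections —
counting Sertoli cells (nuclear SOX9) and pre-meiotic germ cells
(nuclear MAGE-A) per tubule, measuring where they sit, and estimating
how many are dividing — is traditionally done by manual annotation:
slow, observer-dependent and hard to reproduce. `tubuleseg` implements
that workflow as a deterministic pipeline for calibrated multi-channel
TIFF images:

1. **Tubule segmentation** — a multilayer-perceptron pixel classifier
   over multiscale filter features (Gaussian intensity, gradient
   magnitude, structure-tensor coherence, Hessian determinant at
   σ ∈ {1,2,4,8} px) labels pixels `tubule` / `tissue` / `background`;
   8-connected components become ROI polygons after a minimum object
   size of 400 µm² and minimum hole size of 200 µm².
2. **Cell segmentation** — watershed on the distance transform of the
   thresholded counterstain (Hoechst) channel inside each tubule ROI,
   with 5 µm Voronoi-constrained cell expansion. A plugin adapter
   accepts label maps from star-convex CNN detectors.
3. **Classification** — per-cell marker statistics in the marker's
   compartment (nuclear or cytosolic) against intensity thresholds;
   cells matching no rule are `unclassified`.
4. **Spatial organisation** — tubules are split into a
   *membrane-associated* band (within 35 µm of the boundary) and the
   *luminal* remainder; same-class cells with centroids within 15 µm
   form a neighbour graph whose degree distributions expose clustering.
5. **Mitotic indexing** — nuclear Hoechst intensity proxies DNA content
   (2n → 4n); cells above 14,000 RFU (the upper end of the post-mitotic
   Sertoli G1 range, peak ≈ 9,000 RFU) count as mitotically active:
   `index = 100 × n(> threshold) / n`.
6. **Reporting** — counts, densities (cells/mm² tubular area), OLS
   area–count regression and standardised-residual QC flags.

A synthetic-scene generator (`generate_scene()`) emulating tubular
tissue — peritubular rim, interstitium, truncated-normal G1
counterstain with a uniform mitotic tail, per-class marker channels —
provides full ground truth, so every stage is tested without any
imaging data.

## Worked example 1: mitotic-index arithmetic on published pooled counts

The package bundles pooled per-region cell counts from a 13-section
prepubertal human testis experiment
(`inst/extdata/mitotic_counts_by_region.csv`). Rebuilding per-cell
records from the counts and running them through the normal gating path
reproduces the published summary table:

```r
library(tubuleseg)
counts <- read_measurements(system.file(
  "extdata", "mitotic_counts_by_region.csv", package = "tubuleseg"))
mitotic_index(cells_from_counts(counts), 14000)
#>    class   region total   g1 mitotic pct_of_class g1_pct mitotic_index_pct
#> 1 MAGE-A    total 11780 5826    5954        100.0   49.5              50.5
#> 2 MAGE-A membrane  8976 4639    4337         76.2   51.7              48.3
#> 3 MAGE-A  luminal  2804 1187    1617         23.8   42.3              57.7
#> 4   SOX9    total 10124 8977    1147        100.0   88.7              11.3
#> 5   SOX9 membrane  7934 6993     941         78.4   88.1              11.9
#> 6   SOX9  luminal  2190 1984     206         21.6   90.6               9.4
```

Read: germ cells are highly mitotic (50.5 % overall, rising to 57.7 %
in the lumen), Sertoli cells are largely post-mitotic (11.3 %), and
roughly three quarters of both populations sit within 35 µm of the
tubule boundary.

## Worked example 2: a synthetic scene end to end

```r
scene <- generate_scene(scene_spec(seed = 21))
rois  <- roi_set(scene$truth$tubules, rep("tubule", 3), image_id = "demo")
cells <- detect_cells(scene$image, rois)
cells <- classify_cells(cells, classifier_spec(default_class_rules()))
cells <- assign_regions(cells, rois, membrane_depth_um = 35)

mitotic_index(cells, derive_threshold(cells, cycle_config()))
#>    class   region total g1 mitotic pct_of_class g1_pct mitotic_index_pct
#> 1   SOX9    total    74 74       0        100.0  100.0               0.0
#> 2   SOX9 membrane    68 68       0         91.9  100.0               0.0
#> 3   SOX9  luminal     6  6       0          8.1  100.0               0.0
#> 4 MAGE-A    total    76 55      21        100.0   72.4              27.6
#> 5 MAGE-A membrane    65 46      19         85.5   70.8              29.2
#> 6 MAGE-A  luminal    11  9       2         14.5   81.8              18.2

summarise_image(cells, rois)
#>   image_id        class count tubule_area_mm2 density_per_mm2
#> 1     demo       MAGE-A    76      0.03286749        2312.316
#> 2     demo         SOX9    74      0.03286749        2251.465
#> 3     demo unclassified    64      0.03286749        1947.213
#> 4     demo          all   214      0.03286749        6510.994

build_neighbour_graph(cells, neighbour_config(15))
#> NeighbourGraph: 150 nodes, 104 edges (radius 15 um)
```

The scene draws MAGE-A cells mitotic with probability 0.30 and SOX9
cells with probability 0; the recovered indices (27.6 % and 0.0 % at
n = 76 and 74) sit inside binomial sampling error of those parameters,
and the 214 detections match the 214 ground-truth tubule cells
(watershed count recovery is asserted at ±5 % in the tests).

Pixel-classifier training and full orchestration (including YAML
configs and output files) go through `train_pixel_classifier()` /
`predict_pixels()` / `extract_rois()` and `run_pipeline()`; a thin
command-line front end lives at `inst/cli/tubuleseg.R`
(`simulate` and `run` subcommands). The methods vignette
(`vignettes/tubuleseg-methods.Rmd`) documents the model, parameter
defaults, numerical choices and limitations.

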