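---
title: "Methods: automated quantification of seminiferous tubule immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated quantification of seminiferous tubule immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tubuleseg` quantifies multi-channel immunofluorescence sections of
testicular tissue. The analytical chain is:

1. **Tubule segmentation.** A multilayer-perceptron pixel classifier
   assigns every pixel to `tubule`, `tissue` (interstitium) or
   `background` from a bank of multiscale filter responses, and
   connected components are filtered into region-of-interest polygons.
2. **Cell segmentation.** Within each tubule ROI, nuclei are separated
   on the counterstain (Hoechst) channel by a watershed on the Euclidean
   distance transform, then expanded into non-overlapping cell
   boundaries.
3. **Cell classification.** Cells are labelled by marker intensity in
   the marker's subcellular compartment (nuclear SOX9 for Sertoli cells,
   nuclear MAGE-A for pre-meiotic germ cells, cytosolic MVH in mouse
   panels); cells meeting no rule are `unclassified`.
4. **Spatial organisation.** Each tubule is partitioned into a
   membrane-associated band (within 35 µm of the tubule boundary, about
   two cell diameters) and the luminal remainder, and same-class cells
   whose centroids lie within 15 µm are linked into a neighbour graph.
5. **DNA-content gating.** Nuclear counterstain intensity proxies DNA
   content (2n in G1, up to 4n in G2/M). Cells whose nuclear mean
   exceeds 14,000 RFU — the upper end of the G1 range of the
   post-mitotic Sertoli reference population — are counted as
   mitotically active, and mitotic indices are tabulated per class and
   tubule region.
6. **Reporting.** Densities (cells/mm² of tubular area), per-image
   summaries, an ordinary-least-squares area–count surface, and
   flag-not-drop outlier QC.

Because no public imaging data accompany this problem, the package
ships a synthetic-scene generator (`generate_scene()`) with complete
per-pixel and per-cell ground truth; the entire test suite runs against
it.

# The synthetic scene generator

A scene is a calibrated multi-channel raster (default 768×768 px at
0.5 µm/px) containing elliptical tubules with a peritubular rim, an
interstitial band, and background. Defaults were chosen once to emulate
prepubertal human tissue at 20× and are the conditions under which all
quality claims are tested:

* **Geometry.** 3 tubules with semi-axes 45–62 µm and aspect 0.85–1,
  ≥15 µm apart; a 5 µm peritubular rim (included in the tubule region,
  as when myoid cells are annotated into training labels); a 45 µm
  interstitial band. At these prepubertal radii most of the tubule lies
  within 35 µm of the boundary, so membrane-associated cells dominate —
  the same 75–80 % share reported for pooled prepubertal sections.
* **Cells.** Cell radius 4 µm with nuclei rendered at 3.2 µm, placed
  with centre separation ≥ 2.1× the cell radius so nuclei never touch
  (`min_sep_factor` below 2 deliberately produces fused nuclei to
  stress the watershed). Membrane-zone density 7 cells/1,000 µm²
  (mix 35 % SOX9, 35 % MAGE-A, 30 % marker-negative), luminal density
  4/1,000 µm² dominated by MAGE-A cells laid down in rings of five with
  pairwise distances between the placement minimum and 15 µm,
  reproducing the clustered luminal organisation of germ cells;
  interstitial cells are marker-negative.
* **Intensities.** Counterstain G1 nuclei draw from a normal
  (mean 9,000, SD 1,500 RFU) truncated to [6,000, 14,000]; mitotic
  nuclei draw uniformly from [14,000, 30,000]; the default mitotic
  fraction is 0.30 for MAGE-A cells and 0 for SOX9 (Sertoli cells are
  post-mitotic). Marker-positive cells draw N(9,000, 1,500²) truncated
  at 5,000 in their marker channel. Region baselines (background 200,
  interstitium 1,300, tubule cytoplasm 2,400, rim 3,000 RFU) keep the
  dimmest nucleus ≥2× above its local background, as in usable
  counterstain exposures; the rim is a moderate elevation (flattened
  myoid nuclei), deliberately dimmer than true nuclei so it cannot be
  confused with them by the cell segmenter. Channels are blurred by
  0.6 px and carry additive Gaussian read noise (SD 60 RFU).
* **What it does not emulate.** Optical PSF structure, spectral
  crosstalk, staining gradients, tissue damage, folds or out-of-focus
  patches. Passing tests therefore demonstrate correctness of the
  algorithms under clean, calibrated conditions — not robustness to
  acquisition artefacts.

Scenes are bit-reproducible given `seed`; antibody-control renders
(`render_control_image()`) share geometry, cells and counterstain with
the fully stained render at the same seed, with the omitted marker
channels holding baseline plus noise only.

# Pixel classification choices

* **Features.** Per channel and per scale σ ∈ {1, 2, 4, 8} px:
  Gaussian-smoothed intensity, gradient magnitude, structure-tensor
  coherence ((λ₁−λ₂)/(λ₁+λ₂) of the σ-integrated tensor, defined 0 on
  flat fields), and the Hessian determinant. The scale set spans
  nucleus-to-tubule structure at 20×-like calibrations. "Colour" in a
  fluorescence stack is taken to mean per-channel intensity.
* **Network.** One hidden layer of width max(32, 2·n_features),
  logistic activations, softmax output, cross-entropy loss, L2 decay
  1e-4, at most 300 optimiser iterations, fitted by `nnet` under a
  fixed seed after z-scoring features on the training pixels. Training
  pixels are capped (stratified) at 2,000 per class to bound run time.
  Run-to-run identity is exact: training twice with one seed gives
  bit-identical weights, and prediction is a deterministic forward
  pass.
* **Channel lock.** A model refuses images whose channel set differs
  from its training set — marker panels need their own models.
* **ROI extraction.** 8-connected components per class; components
  <400 µm² removed (keep-if-≥, since the tool behaviour the defaults
  come from does not document strictness), holes <200 µm² filled,
  holes ≥200 µm² kept. Background is not emitted as ROIs. Extraction
  is idempotent on its own rasterisation, and tubule priority wins
  when rasterising overlapping polygons. No bridging correction is
  applied between adjacent tubules; a morphological opening could be
  added upstream by the caller if needed.
* **Quality.** Segmentation quality is asserted *after* ROI filtering
  (the pipeline's actual output): per-class pixel IoU ≥ 0.90 on
  default scenes unseen during training.

# Cell segmentation choices

The watershed sequence is: Gaussian blur (σ = 1.5 µm), foreground
threshold, Euclidean distance transform, watershed with seed maxima at
least 7 µm apart, area filter 10–400 µm². The saddle-depth tolerance of
the watershed is kept small (0.3 px): maxima that clear the 7 µm
separation are treated as genuine seeds even when a bright neighbour's
blur skirt makes the saddle between them shallow, which is what
separates a dim G1 nucleus from an adjacent bright mitotic one.

* **Threshold.** Otsu computed on *log* intensities within the ROI. A
  linear-domain Otsu is dragged upward by the long mitotic tail
  (up to ~30,000 RFU) and loses dim G1 nuclei; the log domain
  compresses the tail and lands the cut between cytoplasmic background
  and the dimmest nuclei. A contrast guard rejects thresholds whose
  foreground class is less than 1.5× brighter than the background
  class, so structureless (noise-only) ROIs yield zero detections
  instead of watershed shards. A fixed threshold mode is available for
  exact reproducibility across exposures.
* **Intensity statistics.** Nuclear statistics are measured on the
  nucleus mask eroded by 1.5 µm (when non-empty). The thresholded mask
  necessarily overshoots the nuclear rim into partial-volume pixels;
  without erosion the nuclear mean reads ~10 % low, which would bias
  DNA-content gating. Geometry (area, polygon, centroid) always uses
  the full mask. Cytosolic statistics use the cell-minus-nucleus
  region.
* **Cell expansion.** Nuclei dilate by 5 µm (the conventional default
  of interactive tools), clipped to the ROI and partitioned by nearest
  nucleus (Voronoi propagation), so cells never overlap and each
  contains its nucleus.
* **Star-convex detectors.** The CNN family is supported through a
  plugin adapter (`backend = "plugin"` with a label-map function); the
  package neither ships nor trains CNN weights, and no core result
  depends on them.

# Spatial and cycle choices

* The luminal zone is the inward buffer of the tubule polygon by 35 µm,
  computed on a 0.25 µm raster with a half-pixel offset correction;
  membrane area is reported as tubule minus luminal, making the
  additive identity exact. For a circular tubule of radius 100 µm the
  traced luminal disc and membrane annulus agree with the analytic
  areas within 1 %.
* Region assignment uses the nucleus centroid's distance to the tubule
  boundary; a centroid exactly on the 35 µm line is
  membrane-associated (deterministic tie rule). Tubules narrower than
  twice the depth are entirely membrane-associated.
* Neighbour edges are inclusive (≤15 µm) and restricted to same-class
  pairs; unclassified cells are excluded. Degrees are computed before
  region filtering — a membrane cell can be a luminal cell's
  neighbour — because regions select cells, not edges. Degree
  histograms report the smallest most-frequent degree on ties.
* Mitotic gating is strictly greater-than ("above" the threshold);
  cells at exactly 14,000 RFU are G1. The statistic is the nuclear
  *mean* (configurable): for mean intensity the 2n→4n doubling argument
  is approximate (it is exact for integrated intensity), which is why
  the G1 reference population, not first principles, anchors the gate.
  The alternative `reference_percentile` mode takes a percentile
  (default 97.5) of the reference class — note that for the synthetic
  G1 distribution this lands near 11,900 RFU, noticeably below the
  fixed 14,000 default, because 2.5 % of a truncated normal still sits
  well inside its upper tail; the fixed mode is the faithful default.

# Reporting choices

Cohort statistics (ANOVA and rank tests between experimental groups)
are out of scope; the package reports the OLS area–count surface
(slope, r², two-sided p for the slope) because it is the QC instrument:
images whose standardised residual exceeds |z| > 3 are flagged, never
dropped, keeping exclusions auditable. Standardised residuals make the
flags invariant to area units.

# Problem sizes used in tests

The test suite and acceptance script generate everything they analyse:
six 512 px scenes (2 fully stained + 4 antibody controls, 3 annotations
per class each) train the classifier; one unseen 768 px scene is
segmented for IoU; ten 1152 px scenes (7 tubules each, ~180 MAGE-A
cells per scene, pooled n ≈ 2,000) support mitotic-fraction recovery
within the binomial 99 % CI; one 1024 px two-tubule scene with 78–92 µm
tubules exercises luminal clustering. These sizes were chosen as the
smallest that leave the statistical assertions well-powered.

# Known limitations

* The pixel classifier is trained and validated on synthetic contrast;
  real tissue requires retraining on real annotations (the training API
  is the same).
* Watershed merges truly fused nuclei when the distance-transform
  saddle is shallow; the generator's default spacing avoids this by
  construction, and the plugin adapter exists for harder material.
* RFU scales are instrument-specific: the 14,000 RFU gate transfers
  only to acquisitions calibrated like the source experiment; use the
  reference-percentile mode or a manual gate elsewhere.
* Bridged tubules (densely packed, e.g. mouse) are not split; counts
  are unaffected when no cells lie in the bridge, but per-tubule areas
  would be.
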