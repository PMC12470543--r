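---
title: "Methods: semi-automated red blood cell morphology annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated red blood cell morphology annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcmorph)
```

## The problem

Red blood cell (RBC) morphology — size, shape, staining pattern — carries
much of the diagnostic signal in anemias and hemoglobinopathies, yet
annotating tens of thousands of single cells from stained smears by hand
is slow and observer-dependent. `rbcmorph` implements a hybrid annotation
pipeline for this task: smear regions of interest (ROIs) are screened and
segmented into centred single-cell patches; a quantitative geometric
description is attached to every cell via ellipse fitting; an autoencoder
learns latent features that a k-means sweep groups into morphologically
coherent clusters; human experts then label *clusters* rather than cells;
and deterministic augmentation balances the rare classes. Because real
patient slides are confidential, the package carries a seeded synthetic
smear generator with per-cell ground truth, so every stage is exercised
end-to-end by code alone.

## Synthetic smears as the test bed

`smearScene()` / `generateScene()` emulate the statistical structure the
pipeline assumes rather than the photometric detail of a stained slide:

* **Geometry.** Cells are ellipses with major diameter drawn from
  6–8 µm at the 0.1658 µm/px scanning scale (the normocytic band), aspect
  ratio (AR) from a configurable range (default 1.0–1.15; micro/macro
  outliers and elongated forms are opt-in), random orientation, and a
  central pallor dip that raises the cell centre part-way back toward
  background — the biconcave profile seen in Wright–Giemsa smears.
* **Intensity.** Background ≈ 220, cell body ≈ 120, pallor toward 190,
  additive Gaussian noise (σ = 3 by default). These values were chosen
  once so that Otsu's threshold separates foreground robustly, which is
  all the downstream stages require; they are a stand-in, not a claim
  about any real scanner's histogram.
* **Composition.** Interior cells are placed by rejection sampling with a
  clearance of the sum of semi-major axes, so they never touch; touching
  doublets are planted explicitly at centre distance 0.6–0.9 × the sum of
  semi-minor axes; border cells are centred within a fraction of a
  semi-minor axis of the frame so their bounding box always crosses it;
  debris enters as 2–8 px blobs. Placement failure after a bounded number
  of attempts raises a "scene too dense" error rather than looping.
* **Determinism.** One integer seed drives every draw through a single
  RNG; identical requests are bit-identical, which the test suite relies
  on heavily.

Each generated cell carries its analytic truth: axes, angle, pallor depth
and the morphometric class obtained by running `classifyCell()` on the
analytic descriptors (for a full ellipse the area-completeness ratio is
exactly Lminor/Lmajor). What passing tests on these scenes does **not**
show: robustness to staining gradients, halo artifacts, white-cell
texture, or densely clumped real smears — the generator has no model of
those.

## Extraction

`extractCells()` follows the classical segmentation route: mean-shift
smoothing (an iterative intensity mode filter implemented in C++;
spatial radius 10, range radius 20 by default — both exposed, since no
single setting suits all scanners), grayscale, Otsu binarisation with the
cells on the dark side, connected components, then per-component
treatment:

* components whose bounding box touches the frame route to
  `touching_edge`;
* remaining components are offered to `separateTouching()`, a watershed
  on the Euclidean distance transform. We use a *hierarchical* watershed
  with a peak-prominence tolerance (0.5 px) rather than fixed-radius
  local-maximum markers: deeply overlapped doublets at 0.6 × the sum of
  semi-minor axes can present a single distance maximum or a shallow
  saddle, which fixed-separation peak picking misses, while the
  prominence criterion still refuses to split single cells — including
  pencil forms up to AR 2, whose distance ridge is flat but saddle-free.
  Splits whose smallest region falls below 25 px² are treated as
  unresolvable and routed to `overlapping`;
* successfully split parts become `extracted_cluster`; unsplit components
  are `small` (max bounding-box side ≤ 16 px) or `single`.

"Size" for binning is the larger bounding-box side, read as the canvas
side the patch will occupy: ≤16 → 32 ("small"), then 32/128/256/512/1024,
else native-size "oversize". Patches are centred on black canvases by a
whole-pixel shift (clamped for cells that exactly fill the canvas), which
keeps centring idempotent and pixel-exact. Coordinates are 0-based,
half-open, (row, col); "touches border" means the bounding box meets any
frame edge.

`roiScreen()` gates whole ROIs before extraction: width within
2000–8000 px, implausible foreground (components < 25 px² or solidity
< 0.5) at most 10% of the foreground, and clumped foreground (components
over 3× the median plausible component area) at most 15%. The artifact
bound is quoted as a 5–10% range in the field; we adopt the upper bound
as the operative criterion.

## Ellipse morphometrics

`fitEllipse()` is a direct least-squares conic fit under the ellipse
constraint (Fitzgibbon's method) on centred, scaled contour points;
contours shorter than 5 points are skipped because the conic is
underdetermined. Three descriptors feed classification:

* **AR** = Lmajor / Lminor (full axis lengths, major ≥ minor by
  construction);
* **Lmajor in µm** = Lmajor(px) × pixel size (default 0.1658 µm/px);
* **ER** = cell area / (π (Lmajor/2)²) — the cell's pixel area relative
  to the circle circumscribed on the major axis. A complete near-circular
  cell has ER ≈ 1; fragments, half-cells and broken contours fall well
  below. ER is normative from this closed form; the contour∩ellipse
  intersection area is logged separately as a diagnostic only.

`classifyCell()` applies the printed decision table — shape: AR ≤ 1.05
Circle 095, ≤ 1.10 Circle 090, ≤ 1.20 Circle 080, ≤ 1.40 Oval 060,
≤ 1.60 Oval 040, else Pencil; size: < 6 µm Micro, ≤ 8 µm Normal, else
Macro; area: ER ≤ 0.80/0.90/0.95 bins, else Area 100 — yielding 72
mutually exclusive class paths. Boundaries are inclusive exactly as
printed, and ER values marginally above 1 from rasterisation clamp to 1.
`screenQuality()` drops cells with ER ≤ 0.50 (strict), applied after
metric computation and before file routing, with the `kept` flag recorded
either way.

Numerical choices worth knowing:

* "Cell area" is the foreground pixel count of the filled component mask
  (raster, not polygon). The two agree through Pick's relation — the
  traced boundary polygon area plus half its lattice boundary plus one —
  and the tests assert that identity.
* Contours traced through boundary-pixel centres sit half a pixel inside
  the true outline at each end, biasing fitted axes low by ~0.6 px and ER
  high by ~0.03. The raster pathway therefore adds a 1 px pixel-width
  correction to both axis lengths (`pixelCorrection = 1`); exact
  geometric point sets are fitted uncorrected. With the correction,
  rendered ellipses with semi-axes ≥ 10 px recover axes within 2% and ER
  within 0.01 of Lminor/Lmajor.

## Latent features and clustering

Two autoencoder architectures are provided, both trained with Adam on
the binary cross-entropy reconstruction loss over patches normalised to
[0, 1]: a dense model (flatten → 64-unit ReLU latent → sigmoid
reconstruction) and a convolutional model with two 3×3 conv + 2×2
max-pool stages of 16 and 8 filters, mirrored by conv + nearest-neighbour
upsampling, ending in a sigmoid map. The filter counts are the smallest
mirrored design consistent with that description and are exposed in
`aeConfig()`. Both models are implemented directly on matrix operations
with hand-derived backpropagation; the tests verify the gradients against
finite differences to 1e-6 and bit-reproducibility under a fixed seed.
Training uses a single seeded 80/20 train–validation split (a fold count
is deliberately not invented), and per-epoch losses are logged as
`epoch,train_loss,val_loss`. Grayscale patches are used throughout; RGB
input collapses by channel mean.

The configured defaults (200 epochs, batch 64, 128×128 input) describe a
full run. The test suite and acceptance script train the dense model for
30 epochs on 400 fixture patches and assert the property that actually
matters downstream: latent vectors of two visually distinct shape classes
(normocytic disks vs pencil forms) are linearly separated well enough
that 2-means recovers the classes at ≥ 90% accuracy. Dataset-specific
reconstruction losses of any particular study are not reproducible
without that study's data and are not asserted.

`kmeansLatent()` runs Lloyd iterations from k-means++ starts (10 seeded
restarts, best within-cluster sum of squares kept), on raw Euclidean
latents without scaling. `silhouetteScore()` and `daviesBouldin()`
implement their defining formulas directly — they are contract surfaces,
so the tests pin them to O(n²) brute-force transcriptions within 1e-9
and cross-check silhouette against the `cluster` package. Singleton
clusters contribute 0 silhouette; duplicated centroids make the
Davies–Bouldin ratio undefined and raise an error. `sweepK()` writes one
`k,silhouette,dbi` row per candidate after removing any stale score file;
the optimal k is reported, never chosen silently — on planted partitions
the silhouette argmax and DBI argmin coincide with the true cluster
count. `project2D()` is seeded UMAP (neighbours 15, min-dist 0.1, exact
nearest neighbours, single-threaded) for visual review only; nothing
downstream consumes the embedding.

## Expert labels and augmentation

Cluster review is modelled as a file interface: a CSV of
`cluster_id,class_name,status,reviewer,cycle[,ellipse_filter]` rows.
Assignment is cluster-granular by design — experts validated clusters,
not cells — with two-cycle override semantics (the highest cycle wins).
Confirmed clusters populate `<class>/` directories; mixed or artifact
clusters divert to `_review/`. The optional `ellipse_filter`
(e.g. `shape_group=Pencil`) intersects a cluster's membership with the
morphometric class paths, which is how geometry refines shape classes
such as elliptocytes. The 43-class catalog ships with a reference
distribution of an expert-validated 14,089-image dataset; its printed
percentages are reproduced exactly when the denominator is the sum of the
printed class counts (14,000 — the printed grand total is internally
inconsistent with its own column, and the percentages follow the sum).

`augmentPatch()` expands each patch into S × R × (F + 1) variants: every
scale (cells re-embedded on the black canvas), R evenly spaced rotations
i·(360/R)° (bilinear, black fill; 90° multiples are exact), emitted
unflipped plus per requested flip. The unflipped variant counting toward
the multiplier is forced by the reference plan arithmetic
(50 × 5 × 4 = 1000; 2 × 2 × 250 × 4 = 4000). Scale subsets draw from the
canonical {0.98, 0.99, 1.00, 1.01} list in order. `recenterPatch()`
restores centring after rotation; on clean black backgrounds it isolates
the largest nonzero component and shifts by whole pixels (exactly
idempotent), falling back to mean-shift + Otsu cleanup only when the
border is non-black. `augmentClass()` self-checks that the file count
equals `expectedCount()` and flags plans whose arithmetic cannot reach
their stated target — the shipped 4000-image plans for 125-input classes
print R(4), which yields 2000; the report records the shortfall rather
than silently adjusting R.

## Problem sizes and degenerate inputs

The suite runs at deliberately modest sizes chosen to exercise every
branch: 25–29-cell scenes (600–800 px) for extraction closure, one
2200 px-wide scene for ROI screening, 100-patch fixture sets for
classification closure, 200-sample blob sets for the metric oracles, and
the 400-patch/30-epoch dense autoencoder run. Degenerate inputs have
defined behaviour throughout: constant images are rejected by Otsu
("degenerate histogram") and produce empty extractions with a warning;
empty scenes, empty assignment files and empty class trees yield empty —
not invalid — results; infeasible fixture class combinations (e.g. a
Pencil shape with Area 100 completeness, impossible for any full
ellipse) and over-dense scenes raise informative errors.

## Known limitations

* The synthetic intensity model is minimal; methods that depend on
  staining texture (e.g. pallor-based hypochromia grading) cannot be
  validated against it.
* Watershed separation is only as good as the distance transform:
  doublets of very unequal size or chains overlapping by more than the
  planted range may stay merged (they route to `overlapping`, so they
  are quarantined rather than mislabelled).
* The convolutional autoencoder is CPU-bound and intended for small
  studies; the dense model is the practical default here.
* One ellipse is fitted per connected component; multi-ellipse
  decomposition of merged contours is out of scope.
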