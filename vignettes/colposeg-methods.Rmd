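---
title: "Methods: mask geometry, dataset curation and evaluation in colposeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask geometry, dataset curation and evaluation in colposeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colposeg)
```

## The problem

Colposcopy — the magnified inspection of the cervix after acetic acid and,
optionally, Lugol's iodine staining — produces images whose interpretation
depends heavily on examiner experience. Per-class segmentation models
(one model per anatomical structure, finding, or artifact class) are a
promising assist, but they sit at the end of a long data-engineering chain:
brush-mask annotations exported from CVAT as run-length-encoded (RLE)
payloads must become model-ready polygons, curated class datasets, and
leakage-safe splits; predictions coming back must be scored consistently.
`colposeg` implements that chain. The neural models themselves are
deliberately out of scope: they are pluggable external predictors whose
outputs enter as COCO-style result JSON.

## Masks, contours and the donut problem

A binary mask is a logical matrix; pixel `[r, c]` covers the continuous
square `[c-1, c] × [r-1, r]` with center `(c-0.5, r-0.5)`.

**Coordinate convention.** Contours are traced along pixel *edges*, so
vertices sit on the integer lattice at pixel corners. This is a deliberate
design choice: a crack-boundary polygon contains exactly the centers of
the pixels it encloses, which makes rasterization (even–odd rule on pixel
centers) an *exact* inverse of contour extraction, makes the shoelace area
of a contour equal the exact enclosed pixel count, and makes the connector
bridges introduced by donut merging exactly zero-area. The alternative —
vertices at pixel centers, as some contour extractors return — loses a
half-pixel boundary band on every roundtrip and turns several exact
invariants into approximate ones.

**Connectivity.** Foreground is 8-connected (the convention of mainstream
contour extractors), hence background is 4-connected. Component labeling
reuses `EBImage::bwlabel` (4-connected) and merges diagonally touching
labels with a union–find pass. At a corner where two foreground pixels
touch diagonally, the boundary walk prefers the turn that keeps both
pixels in a single loop; the resulting contour touches itself at that
point but rasterizes correctly. One documented edge case follows: a hole
that touches its outer boundary at a single corner is traced as one
figure-eight loop — pixel recovery stays exact, only the outer/hole
bookkeeping collapses to a single contour.

**Simplification** is Douglas–Peucker on the closed path (anchored at the
vertex farthest from the start), keeping vertices whose deviation from the
simplified path exceeds `tolerance_px + 1e-9`; the epsilon absorbs
floating-point dust so tolerance 0 removes exactly the collinear vertices.
The default tolerance is 0.5 px: at most half a pixel of boundary
deviation, which keeps the pipeline-conservation Dice above 0.99 for
structures of 100 px and more while shedding the stair-step vertices of
crack boundaries.

**Size filter.** Contours with enclosed pixel area strictly below 30 are
discarded; area exactly 30 survives. "Area" is the enclosed pixel count
(not vertex count or perimeter), the reading consistent with the unit in
which masks are measured. Holes fall with their parent. The filter is
applied before donut merging by default; `filter_before_merge = FALSE`
reverses the order for callers who want merged-polygon areas judged
instead.

**Donut merging.** Annular structures — typically squamous epithelium
ringing the external os — cannot be stored as one ordinary polygon, and
storing outer and inner rings as a single naive contour produces visible
artifacts in model predictions. `merge_donut()` splices each hole into the
outer path through a zero-width connector bridge between the closest
vertex pair of the current merged path and that hole (ties break to the
lowest vertex index; holes merge in decreasing area order; hole traversal
is oriented opposite to the outer's). Under the even–odd rule the bridge
contributes two coincident crossings that cancel, so the hole stays empty:

```{r donut}
ring <- empty_mask(60, 60); ring[11:50, 11:50] <- TRUE; ring[26:35, 26:35] <- FALSE
poly <- vectorize_mask(ring)[[1]]
identical(rasterize(poly, 60, 60), ring)
```

Hole containment is verified with a lattice-safe interior probe (the cell
below-right of the hole's top-left vertex, with a jittered-centroid
fallback), because centroids of lattice contours land on integer
coordinates where even–odd ray casting is degenerate.

**Multi-component masks** (findings scattered in disconnected patches) are
split into one instance per 8-connected component, ordered by top-most
then left-most pixel, so distant fragments are never artificially joined.

## RLE codecs

Three dialects are implemented, all exact bijections on masks (property
tested): `cvat-bbox` (alternating runs, row-major within the shape's tight
bounding box, first run background — the brush-mask export convention),
`coco-uncompressed` (column-major, whole frame) and `coco-compressed`
(the LEB128-style base-32 string with second-order deltas). The run
ordering of any particular private export is unverifiable; correctness
here is defined by the roundtrip property, not byte-level agreement.
An all-background mask encodes in `cvat-bbox` as a documented degenerate
payload (empty box, zero runs) rather than an error.

## Dataset curation

Filtering applies, in order: quality-tag rejection (default: "Unusable
image" and "Low quality image"), optional procedural-stage selection
(opt-in, because some classes only exist at specific stages — an
iodine-negative zone is only visible after Lugol's solution),
unannotated-image removal, and a resolution policy. The default policy
keeps the two most frequent (width, height) pairs — clinical archives mix
device generations, and scaling minority resolutions (e.g. 167 × 130
thumbnails against 717 × 539 and 1280 × 960 majorities) harms training —
with frequency ties broken by larger pixel area, then lexicographically,
so the outcome is deterministic.

Per-class datasets come in a *general* variant (label = whole class) and
an *extended* variant (label = class restricted to one attribute value,
e.g. metaplastic squamous epithelium). Background images — images without
the class — teach a one-class model negative evidence; the extended
variant additionally distinguishes *difficult* backgrounds carrying the
class with a different attribute value. Background counts are explicit
per-call parameters defaulting to 0 (a tenth of the positive count is a
reasonable starting point when unsure); requests beyond the pool are
capped with a warning. Sampling is seeded and isolated from the caller's
RNG state.

Splits shuffle units under a seed and assign `floor(n·p)` to each subset
with the remainder distributed train → val → test, so 10 images under the
default 70/20/10 proportions give exactly 7/2/1 and any n divisible by 10
splits exactly. Units are images by default; `group_key = "patient"`
shuffles whole patients instead and refuses (with the offending image
list) to run when patient ids are missing, rather than silently falling
back. Each per-class dataset is split independently; callers wanting one
global split can compute a manifest once and reuse it.

Exports: YOLO-seg label files (one line per instance: 0-based class index
then the normalized (x, y) sequence, fixed 6-decimal formatting; empty
files for backgrounds) and per-subset COCO JSON with category ids derived
from the full vocabulary so they are stable across subsets. Both exports
are byte-deterministic given (set, seed).

## Evaluation

Pixel metrics use TP/FP/FN pixel counts with ε = 10⁻⁸ in every
denominator: Dice `2TP/(2TP+FP+FN)`, IoU `TP/(TP+FP+FN)`, precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`. Applying the epsilon rule literally,
an image where both masks are empty scores 0, not 1. Two identities are
maintained to 10⁻⁹ and property-tested: Dice = 2·IoU/(1+IoU), and Dice is
the harmonic mean of precision and recall.

Per image and class, instances are *unioned* on each side before pixel
metrics — reports carry one record per image per class, and the spread
(± SD) across images is the reported variability. An image with ground
truth but no prediction scores zero (models that omit a mask entirely are
penalized, not skipped). Images whose ground truth lacks the class are
excluded from that class's summary by default; false-positive activity on
them is counted separately (`include_empty = TRUE` scores them instead).
Summaries report mean, sample median and sample SD (n−1; a single record
has SD 0), formatted `mean (median) ± SD`.

Instance-level: predictions pool across images, sort by confidence, and
match greedily one-to-one to the unmatched ground-truth instance of
highest mask IoU at each threshold in {0.50, …, 0.95}; AP uses 101-point
interpolation (the convention implied by the mAP50-95 name) and mAP50-95
is the mean of the ten per-threshold APs. With no ground truth AP is
defined as 0. Instance F1 is evaluated at every observed confidence
cutoff and the maximum reported; with nothing to detect and nothing
predicted it is 1 by convention. The composite tuning objective is
`0.7·F1 + 0.3·mAP50-95`, the blend balancing working-point performance
against overlap-threshold quality.

## Synthetic fixtures

`generate_scene()` draws flat-shaded structures — elliptical cervix,
rectangular ring epithelium (exact annular arithmetic: a 40×40 ring with
a 10×10 hole has exactly 1500 foreground pixels), thin instruments, and
scattered lesion blobs — with later structures overwriting earlier ones,
and annotates exactly the visible pixels. Structure sizes scale with the
frame (ring side 0.4·min(W, H), hole a quarter of the ring; instruments
2.5% × 30% of the frame; three blobs of 10% of the minor dimension) so
every class stays visible at any test size. Default frames are 160 × 120.
A single seeded generator drives each scene; no global RNG state leaks.

`perturb_predictions()` derives predictions from ground truth by integer
shifts, square-kernel dilation/erosion, seeded dropping, and jittered
confidences; the all-zero default returns pixel-exact copies at
confidence 1, and a horizontal shift of k px on a w×h rectangle has the
closed-form IoU `(w−k)/(w+k)`, both of which anchor the end-to-end tests.

What the fixtures do *not* emulate: photographic texture, acetowhitening
dynamics, illumination, inter-annotator disagreement, or realistic class
frequency. Passing tests therefore demonstrate the correctness of the
geometry, curation and scoring machinery — not segmentation difficulty on
clinical images.

## Numerical choices and problem sizes

- ε = 10⁻⁸ in metric denominators; identity checks at 10⁻⁹.
- Simplification tolerance 0.5 px default; collinearity epsilon 1e-9.
- Minimum contour area 30 px, inclusive at the boundary.
- Seeds: every randomized operation takes an explicit seed and restores
  the caller's RNG state.
- Test problem sizes: random-mask codec checks up to 256 × 256; scene
  fixtures 48 × 36 to 160 × 120; split checks at 100 images; mAP oracle
  checks exhaustive over 0–5 predictions × 0–3 ground-truth instances.
  These sizes exercise every code path while keeping the whole suite
  around a minute.

## Known limitations

- Self-touching contours (diagonal pinches, boundary-touching holes) are
  rasterization-exact but reported as single loops, not separate
  outer/hole pairs.
- CVAT dialect coverage is the Images 1.1 mask/tag subset; video dialects
  and non-mask shapes (boxes, polylines) are skipped with warnings.
- COCO roundtrips preserve decoded pixel sets, tags and attributes, but
  not the vocabulary's attribute *value sets* (COCO categories carry no
  attribute schema); reading back yields observed values only.
- `mask_map` pools predictions globally (COCO-style); per-image AP
  averaging is not offered.
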