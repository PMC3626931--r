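---
title: "Object-based image analysis with objlayer: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based image analysis with objlayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(objlayer)
```

## The object layer as processing unit

`objlayer` organizes analysis around segmented *objects* rather than
pixels. The central container is the `ObjectLayer`: an integer label map of
the image's shape in which 0 marks background and each positive value marks
the pixels of one object, together with one record per object (id, outer
contour, pixel count, optional class name, named feature vector). Every
processing step consumes and produces object layers, so intermediate
results are always inspectable (`validate_layer()` re-checks the
map/record bijection and pixel-count agreement at each pipeline stage) and
the final state exports directly to CSV with `export_csv()`.

Digital-topology conventions, fixed once and used everywhere:

* objects are **8-connected**, background is **4-connected** — the standard
  complementary pairing that avoids paradoxical crossings of foreground and
  background diagonals;
* coordinates are 1-based `(row, col)`, matching R matrix indexing;
* when a label map assigns one id to several disconnected components,
  `build_layer()` re-labels each component with a fresh id (continuing past
  the current maximum, in raster order of first occurrence), so an id is
  always one coherent segment;
* empty images and zero-object layers are legal everywhere and propagate as
  empty results.

## Contours and morphometry

An object's contour is the closed chain of its outer boundary pixels,
traced along *crack edges* — the unit-length pixel edges separating the
(hole-filled) object from its surroundings. Interior holes are ignored for
the contour; the `area` feature is the raw pixel count. Diagonal
configurations during the trace are resolved by a left turn, which keeps an
8-connected diagonal pair on a single contour.

Two measurement choices deserve justification:

* **Perimeter in crack edges, not boundary-pixel counts.** A boundary-pixel
  count under-measures corners and makes perimeter ratios drift with
  resolution; crack edges give every axis-aligned rectangle its exact
  analytic perimeter `2(w + h)`.
* **Area as pixel count, not polygonal area.** The form factor is
  `contour_length^2 / area`; with crack-edge perimeter and pixel-count
  area, every `n x n` square scores exactly 16 and every `w x h` rectangle
  `(2(w+h))^2 / (w h)`, which the test suite asserts for all `w, h <= 12`.
  (Whether the polygonal enclosed area would be the better denominator is a
  legitimate open choice; the pixel count is used because it makes the
  analytic values exact and keeps `area` and the form-factor denominator
  identical.)

No lower bound of 16 is claimed for arbitrary shapes: thin diagonal objects
measured in crack edges can exceed or undercut naive isoperimetric
intuitions, which is why the tests pin the rectangle family analytically
instead. For digital disks the form factor converges from above to
`64 / pi` (crack perimeter of a digital disk approaches `8r`), and the
suite checks monotone convergence at radii 20, 40 and 80.

## Topology: discrete Voronoi tessellation

Topological relationships are computed by tessellating the label map:
every pixel (background included) is assigned the id of the object
containing its nearest object pixel. Numerical choices:

* **Exact Euclidean distances between pixel centres**, computed per object
  with a two-pass lower-envelope squared distance transform in C++. Squared
  distances between pixel centres are integers, exactly representable as
  doubles, so cross-object comparisons and ties are exact — no chamfer or
  grid-propagation approximations.
* **Ties go to the lowest object id.** Equidistant pixels must be assigned
  deterministically; ids are iterated ascending and only a strictly smaller
  squared distance reassigns a pixel.
* **`max_distance`** (default unlimited) truncates cells: pixels farther
  than the limit from every object keep id 0. Decreasing it never adds
  neighbour pairs.

Two distinct relations are derived and deliberately kept separate:

* *neighbouring* — the objects' Voronoi cells contain 4-adjacent pixels;
  `voronoi_border` counts those cross-cell pixel-edge pairs (crack edges)
  and is symmetric by construction;
* *touching* — the objects themselves contain 8-adjacent pixels;
  `touching_border` counts, per direction, the object's contour pixels
  8-adjacent to the other object, so it may differ between the two ends of
  a pair while `voronoi_border` may not.

One degenerate corner is worth recording: two objects that touch only
diagonally, with both off-diagonal pixels owned by other objects, can touch
without their cells sharing a 4-adjacent border. The network still records
such pairs (with `voronoi_border = 0`), so "touching implies recorded as a
neighbour" holds universally even in that corner.

The `border_to_<class>` feature counts an object's contour pixels that have
at least one 8-neighbour belonging to *another* object of the named class
— pixels, not crack edges, because the quantity is a contact proxy over
the contour-pixel chain; it is therefore bounded by the contour pixel
count, which the tests assert.

## Stain deconvolution

Color deconvolution unmixes RGB optical densities into per-stain
concentrations. Conventions: log base 10, reference intensity 255, and a
guard of `+1` inside the log — `OD = -log10((I + 1) / 255)` — so a zero
intensity stays finite. The default stain matrix carries the standard
published hematoxylin and DAB vectors with the residual channel as their
normalized cross product; rows are re-normalized to unit norm and the
matrix must be invertible. Negative unmixed concentrations are clipped to
zero (physical non-negativity); a white pixel (OD slightly negative under
the `+1` guard) unmixes to all-negative concentrations and clips to exact
zeros.

The forward model used by the synthetic generator and the round-trip tests
is the exact inverse of this definition, `I = 255 * 10^-OD - 1`, so
mix-then-unmix recovers concentrations to machine precision wherever no
channel saturates. On real 8-bit images quantization adds an error of order
`1/(I ln 10)` per channel; the per-object `mean_<stain>` features average
over many pixels, and the packaged Ki67 rule separates positive from
negative nuclei by two orders of magnitude in `mean_DAB`, so quantization
is immaterial there. `mean_hematoxylin`/`mean_DAB` are exposed as OD-space
concentrations (not back-transformed 0–255 intensities); the OD scale is
the one in which stain amounts are additive.

## Segmentation

The segmentation stack is intentionally plain: Otsu thresholding (256-bin
histogram, maximal between-class variance, deterministic lowest-threshold
tie-break, an error on constant input), 8-connected component labelling in
raster order, a minimum-area filter, and — for multi-channel fluorescence —
a priority merge in which each requested channel is thresholded and
componentized independently and pixels claimed by several channels go to
the highest-priority channel (priorities: bone 0, osteoclast 1, monocyte 2
in the packaged chain). Components are labelled *after* conflict
resolution, so the result is independent of the order in which channel
specifications are listed.

Known limitation, stated rather than hidden: touching objects within one
channel are not split. Contour-based nucleus detectors with concave-point
separation exist and would slot in as another layer-producing step; the
shipped stack keeps every stage simple enough to verify against brute-force
oracles.

## Classification and pipelines

Classification never alters geometry: threshold rules
(`gt`/`ge`/`lt`/`le`, explicit because boundary handling must be
deterministic), feature-range object models (closed intervals,
conjunction over predicates), and the interaction rule — source-class
objects with `border_to_<target>` strictly greater than zero are
reclassified — only rewrite class names. Rules apply in chain order and
later assignments overwrite earlier ones, which is exactly how the staged
refinements (tumor/normal, then Ki67+/− within tumors) are expressed.

Chains are declarative JSON (`{"name", "seed", "steps": [{"step",
"args"}]}`) over a registry of named steps, not embedded source code:
pinning a step name plus its arguments reproduces a run exactly, and
`run_chain()` is bit-reproducible for identical (chain, image, seed) —
replicated runs produce byte-identical label maps and CSVs. The trade-off
is that a chain cannot carry a modified copy of a step's implementation;
behavioural variants must be registered as steps. Each executed step is
validated (`validate_layer()`) and logged with its argument map, object
count and class counts. The packaged demonstration chains' thresholds
(segmentation at stain-OD sum 0.15, tumor at area 80, Ki67+ at `mean_DAB`
0.15) are illustrative settings matched to the synthetic scenes below, not
clinically calibrated values.

## What the synthetic generators emulate — and what they do not

`gen_ihc()` emulates a bright-field H-DAB field: white background, large
roughly elliptical tumor nuclei (semi-axes 6–9 px) with hematoxylin 0.45–
0.75 OD, DAB 0.35–0.6 OD on the Ki67-positive fraction, and small
spindle-shaped stromal nuclei (semi-axes ~5 × ~2 px), all placed by seeded
rejection sampling with ≥ 3 px gaps. `gen_fluor()` emulates a two-photon
bone field: a blue bone band (~22% of the image height, wavy top edge),
green osteoclast blobs — a prescribed number placed exactly edge-adjacent
to bone, the rest with ≥ 3 px clearance — and red monocytes at ≥ 10 px
from bone, on dim uniform background noise (0–25) with bright object
pixels (180–240) so per-channel Otsu recovers the geometry pixel-exactly.
Default scene sizes are 256 × 256 with 6 + 8 + 10 (IHC) and 1 + 7 + 5
(fluorescence) objects; the invariant corpora use 100 random layers up to
64 × 64 with up to 10 objects. These sizes keep every brute-force oracle
exhaustive while exercising all code paths.

What passing these fixtures shows: the data model, tessellation, features,
rules and chain engine are correct and deterministic end-to-end. What it
does not show: performance on real tissue — no overlapping or touching
nuclei, no focal blur, no staining artifacts or intensity gradients, no
whole-slide scale. The generators exist to make class, count and contact
recovery *exact and assertable*, not to be realistic.

## Degenerate inputs and errors

Constant channels raise a degenerate-histogram error (Otsu is undefined);
zero-pixel images short-circuit to empty layers; tessellating an empty
layer is an error (there is no nearest object); unknown ids, shape
mismatches, missing features, unknown steps and malformed arguments raise
classed conditions (`objlayer_*`) carrying the offending id or step index.
Label maps write losslessly to 16-bit TIFF; PNG output is limited to 8-bit
ids (the error message redirects larger maps to TIFF).

## Known limitations

* No splitting of touching same-channel objects (above).
* Voronoi tessellation is 2-D, unweighted, non-periodic.
* `border_to` is a pixel-count proxy for interface length, not a geometric
  arc length.
* Texture features and multi-resolution features are out of scope; the
  feature registry covers morphometry, channel/stain intensities and
  class-relational features.
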