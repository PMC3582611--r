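---
title: "Stitching tiled 3D volumes: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching tiled 3D volumes: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitch3d)
```

## The problem and its assumptions

A tiled acquisition is an `R × C` grid of 3D tiles, each stored as an
ordered sequence of 2D grayscale TIFF slices along the depth axis D; the
in-slice axes are V (rows) and H (columns). The stage records a nominal
position for every tile, embedded in the directory and file names. The
model behind this package makes three assumptions:

* **Translation only.** Tiles are parallel along D; the unknown per-tile
  error is a small integer translation (stage drift), not a rotation or a
  scale change. Tiles needing resampling are out of scope.
* **Bounded drift.** The nominal coordinates are wrong by at most a few
  voxels, so the true displacement of each adjacent pair lies inside a
  small search window centered on the nominal alignment, and overlaps
  predicted from nominal coordinates really exist.
* **Sparse content.** Specimens are selectively labeled: parts of the
  volume may contain no structure at all, so any similarity score must
  come with a reliability estimate, and the global placement must tolerate
  pairs whose displacement could not be measured.

All voxel coordinates in the package are 0-based and intervals half-open;
this is stated once here and relied on everywhere.

## Pairwise displacement estimation

For each adjacent pair, the nominally overlapping region of both tiles is
extracted (expanded by the search half-width `delta_search` along the two
non-adjacency axes, clipped at tile borders, so every shift in the window
compares valid data) and condensed into three maximum intensity
projections, one along each axis. Projections keep the thin, bright
structures that drive registration while reducing each comparison to 2D.
Tiles are split along D into substacks of `n_slices` slices and each
substack pair is aligned separately: projections of a full, deep stack
would accumulate too much content to correlate sharply, and the redundancy
across substacks means a content-free stretch of the volume does not doom
the pair.

Each pair of homologous MIPs yields a normalized cross-correlation map
over integer shifts `(u, v)` with `|u|, |v| ≤ delta_search`. The score at
each shift is the zero-mean NCC over the intersection of the two images
after the shift — equivalently the Pearson correlation of the overlapping
pixels, a fact the test suite uses as an independent oracle. Two
conventions are deliberate:

* **Zero variance scores 0.** A constant operand carries no alignment
  information; scoring it 0 (rather than erroring or propagating NaN)
  keeps maps defined on empty regions and flows naturally into a zero
  reliability. A fully constant image pair is additionally flagged
  degenerate.
* **Ties break toward the smallest shift.** Nominal coordinates are
  trusted to within a small drift, so among equally good correlations the
  one closest to the nominal alignment is preferred (smallest Euclidean
  shift, then lexicographic — fully deterministic).

The map from the MIP along D resolves V and H; along V resolves H and D;
along H resolves V and D. Each map peak therefore contributes one
candidate displacement to each of its two directions: six candidates, two
per direction. The search window is applied independently per map; the
candidate offset is reported relative to the nominal alignment.

### Reliability

Two properties of an NCC peak predict whether its shift is trustworthy:
its height (higher is better) and its width (narrower is better). The
width along a map axis is the contiguous run of cells through the peak
with value at least `width_fraction` of the peak (default 0.75, exposed in
`align_config()`); each candidate uses the width along the axis that
corresponds to its own direction. The two measures combine as

```
r = max(0, peak) * (s - w) / (s - 1),    s = 2 * delta_search + 1
```

which is 0 for any non-positive peak, equals the peak value for a
single-cell-wide peak, is monotone increasing in the peak and decreasing
in the width, and stays in [0, 1]. The linear width discount is the
simplest form with those properties; any alternative with the same
monotonicities could be substituted without touching the rest of the
pipeline. Note a practical consequence: at small `delta_search` the
discount is steep (one extra cell of width at `s = 7` costs 17% of the
score), so search windows should not be made smaller than the drift bound
requires.

### Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `n_slices` | substack depth along D (slices) | 100 | typical 100–200; smaller = finer redundancy, more NCC maps |
| `delta_search` | search half-width (voxels) | 16 | must be ≥ the largest plausible pair offset; the overlap must exceed `2·delta_search` along the adjacency axis for the MIP maps to be searchable |
| `width_fraction` | peak-width threshold fraction | 0.75 | |
| `reliability_threshold` | pair acceptance threshold | 0.7 | values in [0.7, 0.8] work well on typical data; lower for very noisy or low-contrast acquisitions |
| `n_levels` | pyramid halving steps | 5 | slice-group size is `2^n_levels` = 32 |

## Projection, thresholding, and what "offset" means

Per-substack estimates collapse to one displacement per pair by taking,
for each direction independently, the estimate with the highest
reliability in that direction (ties to the earliest layer); the result may
mix substacks across directions, which is valid precisely because each
direction carries its own reliability.

Offsets are stored throughout as *corrections relative to the nominal
stage displacement*: an offset of 0 means "exactly where the stage said".
Thresholding a pair whose aggregate reliability falls below the threshold
therefore sets its offsets to 0, its reliabilities to 0, flags it
`default` and nonstitchable — which is exactly the reestablishment of the
stage-coordinate default. The aggregate is the minimum across directions
by default (a single bad axis misplaces a tile; the mean is available via
`threshold_config(aggregate = "mean")`). The comparison is `≥` keeps,
`<` rejects. Whether thresholding should instead act per direction is
genuinely open; per-pair was chosen because a pair with one unmeasurable
axis has not really been registered, and the switchable aggregate keeps
the alternative reachable.

## Global placement

Per direction, tiles form a graph whose edges are the adjacent pairs with
weight `1 / reliability` — infinite (an exact sentinel ordered above every
finite weight, not an overflow) when the reliability is 0. The minimum
spanning tree picks the globally cheapest set of displacements connecting
all tiles without cycles; accumulating nominal-plus-offset along the tree
from the anchor tile (0,0) gives absolute positions. Infinite edges enter
the tree only when a tile or group is reachable no other way, and then
contribute the nominal displacement. Kruskal's algorithm with
lexicographic tie-breaking makes the result deterministic. The gauge is
fixed by anchoring at tile (0,0) and translating so each direction's
minimum coordinate is 0; placements are therefore invariant under global
translation of the nominal coordinates (property-tested). The three
directions are solved independently — three trees, possibly different.

No least-squares relaxation over all edges is attempted: the MST uses each
selected displacement exactly and routes around unreliable ones, which is
the intended behavior when reliabilities are meaningful.

## Fusion and the pyramid

Final slices are assembled stripe by stripe: within a tile row, tiles fuse
left-to-right along H; completed row stripes fuse top-to-bottom along V.
Non-overlap pixels are verbatim copies. Across each overlap the two
sources combine with complementary sinusoidal weights
`w1 = (1 + cos πt)/2`, `w2 = 1 − w1`, where `t` runs from 0 at the first
image's edge to 1 at the second's across the full overlap width (a
single-pixel overlap uses `t = 0.5`). The weights sum to one, so blending
identical data is the identity and fused values never leave the range
spanned by the sources. At four-tile corners the H-then-V order composes
the two weight profiles into an effective 2D product — a deliberate
simplification over explicit four-way blending, noted here because the
result at corners depends on the fusion order. Blending `"none"` cuts
hard at the overlap midpoint, which makes residual misalignment visible in
previews.

Tiles are blended only in-slice; along D a tile contributes its slice
wherever its placed D interval covers the output index, and slices not
covered by a tile stay background. The pyramid halves each axis per level
by averaging 2×2×2 cubes, accumulating in floating point and rounding
half-to-even to the input bit depth only on write. Odd trailing
rows/columns/slices form truncated blocks averaged over the available
voxels, keeping the pyramid self-similar; exact mean preservation across
levels consequently holds when every level's dimensions are even, and to
within rounding otherwise.

## Memory and I/O contracts

Both data-touching steps are streamed and instrumented
(`io_stats()` / `reset_io_stats()`):

* Alignment walks the grid row-wise when `n_rows ≥ n_cols` (else
  column-wise), releasing each substack as soon as its South and East
  pairs are done, so at most `min(n_rows, n_cols) + 1` substacks of
  `n_slices` slices are resident and each slice file is opened exactly
  once per step. The tests assert both counters.
* Merging processes `2^n_levels` output slices per group (32 at the
  default 5 levels), reading each contributing tile slice on demand, so
  resident output never exceeds one group and each level is written
  exactly once.

These contracts — not any algorithmic cleverness — are what let the
pipeline scale to volumes that dwarf memory; they also make slice-group
parallelism possible in principle, though this implementation is
single-process.

## The synthetic generator: what it emulates and what it does not

`make_phantom()` draws bright curvilinear filaments (smoothed random
walks with a one-voxel halo) and Gaussian blobs on a dark background —
high-frequency structure resembling labeled neurites and somata, the
content regime MIP-NCC is designed for. An optional contiguous slab is
kept background-only to emulate information-free regions.
`tile_phantom()` cuts the phantom into an overlapping grid, displacing
each crop by an integer jitter drawn uniformly on
`[-jitter_max, jitter_max]` per direction (the anchor tile gets zero, and
crops carry a `jitter_max` margin inside the phantom so jitter never runs
out of data), then adds independent Gaussian noise per tile, clipped to
the 8-bit range — so the two copies of an overlap differ, as in real
repeated acquisitions. Integer jitter makes the ±1-voxel recovery
criterion crisp.

The generator does *not* simulate optical PSFs, illumination or
vignetting fields, bleaching, tile rotation, or structured noise. Passing
the recovery benchmark therefore demonstrates the estimator's correctness
under translation-plus-noise, not robustness to shading gradients or
geometric distortion; on real data with strong vignetting, flat-field
correction should precede stitching.

## Problem sizes used in validation

The standard recovery benchmark is a 3×3 grid of 128×128×150-voxel tiles
with 24-voxel overlap, jitter up to ±5 voxels, noise σ=15 against ~180 of
content amplitude (SNR ≈ 12), aligned with `n_slices = 100` (two substack
layers) and `delta_search = 11`: with a 24-voxel overlap the NCC
precondition (image side strictly greater than `2δ`) caps the usable
half-width at 11, which still covers the largest possible pair offset of
±10. On this benchmark every selected per-pair offset matches the injected
ground truth exactly, well inside the ±1-voxel tolerance the recovery
check allows. Unit
tests run on smaller grids (tiles of 20–40 voxels per side) chosen to keep
the full suite under half a minute; phantom content density is raised on
the smallest fixtures so overlaps are never accidentally empty — an empty
overlap is itself a tested behavior (zero reliability), not a registration
failure.

## Degenerate inputs and numerical notes

* Constant overlap regions: flagged degenerate, candidates get offset 0
  and reliability 0; never an exception.
* Overlaps too thin to search (side ≤ `2·delta_search` after projection):
  the affected map contributes unreliable zero candidates; the other maps
  may still resolve their directions.
* A 1×1 grid has no pairs; placement returns the single tile at the
  origin and merging is the identity.
* XML round-trips are canonical: numbers are written with the shortest of
  15/17 significant digits that parses back exactly, so re-saving a loaded
  state is byte-identical — convenient for diffing hand edits.
* Reliabilities outside [0, 1] in a hand-edited file are rejected on load
  with the offending element named.
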