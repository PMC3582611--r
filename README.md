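# stitch3d

Stepwise 3D stitching of tiled light-microscopy volumes in R.

Modern light-sheet and confocal acquisitions cover specimens larger than
the microscope's field of view by recording a grid of overlapping 3D tiles,
each a stack of 2D TIFF slices, with approximate stage coordinates encoded
in the directory layout. Stage coordinates are good to within a small drift
but not good enough to assemble the image directly, so the tiles must be
registered against each other and fused. `stitch3d` implements the complete
pipeline for this problem with memory bounded by tile-row-sized slice
groups rather than by the volume, so arbitrarily deep volumes can be
processed on a workstation. It is aimed at microscopists and image-analysis
engineers who need a scriptable, inspectable stitcher whose every
intermediate result can be checked and corrected by hand.

## Method

The pipeline is a chain of six separable steps, each of which reads and
writes an editable XML state file:

1. **import** — scan the two-level directory hierarchy (first level encodes
   the V stage position, second level V_H, slice files V_H_D), verify the
   grid is complete and convert nominal stage coordinates to voxels.
2. **align** — for every pair of adjacent tiles and every substack of
   `n_slices` slices along depth, condense the nominally overlapping region
   of both tiles into three maximum intensity projections (along V, H, D)
   and compute a 2D normalized cross-correlation map over a
   `(2δ+1) × (2δ+1)` search window for each pair of homologous MIPs. Each
   map resolves two of the three directions, giving six candidate
   displacements per substack pair — two per direction. A candidate's
   reliability in [0, 1] is its NCC peak value discounted by the peak
   width `w`:

   `r = max(0, peak) × (s − w) / (s − 1)`, with `s = 2δ + 1`,

   so a high, sharp correlation peak is trusted and a low or flat one is
   not. Per direction, the more reliable of the two candidates is kept.
   Tiles are streamed a layer at a time so at most
   `min(n_rows, n_cols) + 1` substacks are ever resident and every slice
   file is read exactly once.
3. **project** — collapse the redundant per-substack estimates of each pair
   to a single displacement by taking, per direction independently, the
   estimate with the highest reliability.
4. **threshold** — pairs whose aggregated reliability (minimum over the
   three directions by default) falls below a threshold (default 0.7)
   revert to the stage-coordinate displacement with reliability 0 and are
   marked nonstitchable; a tile all of whose incident pairs are
   nonstitchable is itself nonstitchable.
5. **place** — per direction, build the graph of tiles with edge weights
   `1 / reliability` (infinite for reliability 0) and accumulate the
   displacements along its minimum spanning tree from the anchor tile
   (0,0), so the globally most reliable chains of evidence determine every
   tile's absolute position and unreliable pairs are routed around.
6. **merge** — fuse the placed tiles slice by slice, stripe by stripe, with
   two complementary sinusoidal blending weights
   `w1 = (1 + cos πt)/2`, `w2 = 1 − w1` across each overlap, and write a
   multiresolution pyramid where every coarser voxel is the mean of a
   2×2×2 cube of the finer level. Slices are processed in groups of
   `2^n_levels` (32 for the default 5 levels), which bounds the resident
   output.

A synthetic-data module generates structured phantoms and cuts them into
jittered, noisy tile hierarchies with known ground truth, so the whole
pipeline is testable without any acquisition.

## Worked example

Simulate a 2×2 grid of 60×60×20 tiles with 16-voxel overlap, ±3-voxel
stage jitter and additive noise, then stitch it:

```r
library(stitch3d)

phantom <- make_phantom(c(120, 120, 30), content_density = 1, seed = 42)
sim <- tile_phantom(phantom, n_rows = 2, n_cols = 2,
                    tile_shape = c(60, 60, 20), overlap_vh = c(16, 16),
                    jitter_max = 3, noise_sigma = 5, seed = 7,
                    out_path = file.path(tempdir(), "demo"))

state <- align_volume(sim$volume, align_config(n_slices = 20, delta_search = 7))
state <- project_displacements(state)
state <- threshold_displacements(state, threshold_config(0.7))
stitchability_report(state)
```

```
stitchability map (2 x 2 tiles): S = stitchable, . = nonstitchable
  S S
  S S

pair               axis stitch        off_V     off_H     off_D     r_V     r_H     r_D
(0,0)-(0,1)        H ok               -2        -1         3   0.845   0.725   0.853
(0,0)-(1,0)        V ok                0         3        -2   0.949   0.992   0.992
(0,1)-(1,1)        V ok                5        -1        -1   0.993   0.978   0.993
(1,0)-(1,1)        H ok                3        -5         4   0.782   0.989   0.989
```

Every pair passed the 0.7 reliability threshold, and the offsets (the
corrections to the nominal stage displacement, in voxels) match the jitter
the simulation actually injected — `true_pair_offsets(sim$ground_truth)`
lists exactly the same (V, H, D) triples. Placement and fusion:

```r
state <- solve_placement(state)
state$placements
#>   row col  v  h d
#> 1   0   0  2  0 2
#> 2   0   1  0 43 5
#> 3   1   0 46  3 0
#> 4   1   1 49 42 4
write_pyramid(state, merge_config(n_levels = 2), file.path(tempdir(), "fused"))
```

which writes three resolution levels, `RES(109x103x25)`, `RES(55x52x13)`
and `RES(28x26x7)`, each a directory of TIFF slices.

The same pipeline is available from a shell through
`inst/cli/stitch3d.R` (`--import/--align/--project/--threshold/--place/
--merge`, with `--subvoldim`, `--search`, `--threshold-value`,
`--resolutions` and `--R0/--R1/--C0/--C1/--D0/--D1` subvolume selectors),
with XML state between invocations so a run can be stopped, the metadata
edited in a text editor, and resumed.

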