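Package: stitch3d
Title: Stepwise 3D Stitching of Tiled Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stitches tiled 3D light-microscopy acquisitions stored as
    two-level directory hierarchies of TIFF slice stacks. Pairwise tile
    displacements are estimated by normalized cross-correlation of maximum
    intensity projections of the nominally overlapping regions, with
    per-direction reliability scores derived from the correlation peak value
    and peak width. Redundant per-substack estimates are projected to one
    displacement per adjacent pair, unreliable pairs fall back to stage
    coordinates, and globally consistent tile placements are obtained from a
    per-direction minimum spanning tree over inverse-reliability edge
    weights. Placed tiles are fused stripe-by-stripe with sinusoidal
    blending into a multiresolution pyramid, streaming slice groups so that
    memory stays bounded regardless of volume size. Pipeline state is
    checkpointed to editable XML between steps, supporting manual
    correction and subvolume previews. A synthetic phantom generator
    produces jittered, noisy tiled hierarchies with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
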