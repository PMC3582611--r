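# Streaming fusion of placed tiles into a multiresolution image.
#
# Slices of the final image are assembled stripe by stripe: within a tile
# row, adjacent tiles are fused along H; the row stripes are then fused
# along V. Overlaps are blended with two sinusoidal weights phase-shifted
# by pi (complementary, summing to one); non-overlap regions are verbatim
# copies. Fused slices are produced in groups of 2^n_levels so each level
# of the pyramid (2x2x2-mean downsampling per step) can be emitted while
# only one group is ever resident.

#' Merge configuration
#'
#' @param n_levels Number of halving steps in the pyramid; the full
#'   resolution is level 0 and the coarsest level is reduced `2^n_levels`
#'   times per axis. Slices are processed in groups of `2^n_levels` (32 for
#'   the default 5, which is enough reduction for efficient access).
#' @param blending `"sinusoidal"` (default) or `"none"` (hard cut at the
#'   overlap midpoint; useful to make residual misalignments visible in
#'   previews).
#' @param output_layout `"single_stack"` (each level a flat directory of
#'   slices) or `"multi_stack"` (each level re-tiled into the same
#'   two-level directory dialect as the input, for selective access).
#' @param multistack_dims Integer length-2 (V, H) size of output sub-stacks
#'   when `output_layout = "multi_stack"`.
#' @return A `merge_config` list.
#' @export
merge_config <- function(n_levels = 5, blending = c("sinusoidal", "none"),
                         output_layout = c("single_stack", "multi_stack"),
                         multistack_dims = c(256L, 256L)) {
  stopifnot(n_levels >= 0)
  structure(list(n_levels = as.integer(n_levels),
                 blending = match.arg(blending),
                 output_layout = match.arg(output_layout),
                 multistack_dims = as.integer(multistack_dims)),
            class = "merge_config")
}

#' Sinusoidal blending weights
#'
#' Complementary weights for blending two overlapping images along the
#' normalized overlap coordinate `t` (0 at the first image's side, 1 at the
#' second's): `w1 = (1 + cos(pi t)) / 2`, `w2 = (1 - cos(pi t)) / 2`. They
#' sum to one everywhere and `w1` decreases monotonically.
#'
#' @param t Numeric vector in `[0, 1]`.
#' @return List with `w1` and `w2`.
#' @export
blend_weights <- function(t) {
  stopifnot(all(t >= 0 & t <= 1))
  w1 <- (1 + cos(pi * t)) / 2
  list(w1 = w1, w2 = 1 - w1)
}

#' Fuse two overlapping regions
#'
#' Per-pixel convex combination `w1 * a + w2 * b` with `t` running across
#' the full overlap width along the stated axis, from the `a` side to the
#' `b` side. With `blending = "none"`, pixels with `t < 0.5` come from `a`
#' and the rest from `b` (hard cut at the midpoint).
#'
#' @param region_a,region_b Numeric matrices of identical shape.
#' @param axis `"V"` (t runs along rows) or `"H"` (along columns).
#' @param blending `"sinusoidal"` or `"none"`.
#' @return The blended matrix.
#' @export
fuse_pair_region <- function(region_a, region_b, axis = c("V", "H"),
                             blending = "sinusoidal") {
  axis <- match.arg(axis)
  if (!identical(dim(region_a), dim(region_b)))
    stop_usage("overlap regions have different shapes")
  w <- if (axis == "V") nrow(region_a) else ncol(region_a)
  t <- if (w == 1) 0.5 else (seq_len(w) - 1) / (w - 1)
  if (blending == "none") {
    wt <- ifelse(t < 0.5, 1, 0)
  } else {
    wt <- blend_weights(t)$w1
  }
  if (axis == "V") {
    region_a * wt + region_b * (1 - wt)
  } else {
    sweep(region_a, 2, wt, `*`) + sweep(region_b, 2, 1 - wt, `*`)
  }
}

# Fuse an incoming image into a canvas along one axis. The canvas carries a
# logical mask of already-written pixels; the overlap band is the incoming
# extent that precedes the current front (the rightmost/bottommost written
# coordinate), blended only where the canvas is valid.
.fuse_into <- function(canvas, mask, img, at, axis, front, blending) {
  nv <- nrow(img); nh <- ncol(img)
  rows <- at[1] + seq_len(nv)
  cols <- at[2] + seq_len(nh)
  ov <- if (axis == "H") front - at[2] else front - at[1]
  sub_m <- mask[rows, cols, drop = FALSE]
  old <- canvas[rows, cols, drop = FALSE]
  new <- img
  if (ov > 0) {
    ov <- min(ov, if (axis == "H") nh else nv)
    idx <- seq_len(ov)
    if (axis == "H") {
      blended <- fuse_pair_region(old[, idx, drop = FALSE],
                                  img[, idx, drop = FALSE], "H", blending)
      valid <- sub_m[, idx, drop = FALSE]
      new[, idx][valid] <- blended[valid]
    } else {
      blended <- fuse_pair_region(old[idx, , drop = FALSE],
                                  img[idx, , drop = FALSE], "V", blending)
      valid <- sub_m[idx, , drop = FALSE]
      new[idx, ][valid] <- blended[valid]
    }
  }
  canvas[rows, cols] <- new
  mask[rows, cols] <- TRUE
  list(canvas = canvas, mask = mask)
}

#' Fuse one group of final slices
#'
#' Produces the fused slices for the given global z indices of a placed
#' volume. For each slice, every tile row contributes a horizontal stripe
#' (adjacent tiles fused along H); stripes are then fused along V. Tiles
#' whose placed D interval does not cover a z contribute nothing there
#' (background remains 0). Non-overlap regions are verbatim copies of the
#' tile data.
#'
#' @param state A `stitch_state` at stage `placed`.
#' @param z_group Integer vector of global 0-based slice indices (at most
#'   `2^n_levels` of them when called from [write_pyramid()]).
#' @param config A [merge_config()].
#' @param row_range,col_range Optional half-open tile ranges (preview).
#' @return List of numeric matrices (one fused slice per z, floating
#'   point, unrounded), with attributes `footprint_v`, `footprint_h` and
#'   `origin` describing the output frame.
#' @export
fuse_slice_group <- function(state, z_group, config = merge_config(),
                             row_range = NULL, col_range = NULL) {
  .require_stage(state, "placed", "merge")
  vol <- state$volume
  pl <- state$placements
  if (is.null(row_range)) row_range <- c(0L, vol$n_rows)
  if (is.null(col_range)) col_range <- c(0L, vol$n_cols)
  sel <- pl$row >= row_range[1] & pl$row < row_range[2] &
    pl$col >= col_range[1] & pl$col < col_range[2]
  pl <- pl[sel, , drop = FALSE]
  if (nrow(pl) == 0) stop_usage("empty subvolume selection")
  v0 <- min(pl$v); h0 <- min(pl$h)
  fp_v <- max(pl$v + vol$tile_height_v) - v0
  fp_h <- max(pl$h + vol$tile_width_h) - h0

  the$peak_fused_slices <- max(the$peak_fused_slices, length(z_group))
  slices <- vector("list", length(z_group))
  rows_sel <- sort(unique(pl$row))
  for (si in seq_along(z_group)) {
    z <- z_group[si]
    canvas <- matrix(0, fp_v, fp_h)
    mask <- matrix(FALSE, fp_v, fp_h)
    v_front <- -Inf
    for (r in rows_sel) {
      prow <- pl[pl$row == r, , drop = FALSE]
      prow <- prow[order(prow$col), , drop = FALSE]
      sv0 <- min(prow$v) - v0
      sh0 <- min(prow$h) - h0
      s_nv <- max(prow$v + vol$tile_height_v) - v0 - sv0
      s_nh <- max(prow$h + vol$tile_width_h) - h0 - sh0
      stripe <- matrix(0, s_nv, s_nh)
      smask <- matrix(FALSE, s_nv, s_nh)
      h_front <- -Inf
      any_tile <- FALSE
      for (i in seq_len(nrow(prow))) {
        tp <- prow[i, ]
        zk <- z - tp$d
        if (zk < 0 || zk >= vol$n_slices_total) next
        tile <- vol_tile(vol, tp$row, tp$col)
        img <- .read_slice(file.path(vol$root_path,
                                     tile$slice_paths[zk + 1]))
        at <- c(tp$v - v0 - sv0, tp$h - h0 - sh0)
        res <- .fuse_into(stripe, smask, img, at, "H", h_front,
                          config$blending)
        stripe <- res$canvas; smask <- res$mask
        h_front <- max(h_front, at[2] + vol$tile_width_h)
        any_tile <- TRUE
      }
      if (!any_tile) next
      res <- .fuse_into(canvas, mask, stripe, c(sv0, sh0), "V", v_front,
                        config$blending)
      # stripe carries zeros where no tile covered z; restrict validity
      canvas <- res$canvas; mask <- res$mask
      v_front <- max(v_front, sv0 + s_nv)
    }
    slices[[si]] <- canvas
  }
  attr(slices, "footprint_v") <- fp_v
  attr(slices, "footprint_h") <- fp_h
  attr(slices, "origin") <- c(v0, h0)
  slices
}

#' One 2x2x2 mean-downsampling step
#'
#' Each output voxel is the arithmetic mean of its 2x2x2 block of the input
#' (the mean of an 8-voxel cube). Odd trailing rows/columns/slices form
#' truncated blocks whose mean is taken over the available voxels, keeping
#' the pyramid self-similar.
#'
#' @param volume_group 3D numeric array (V, H, D).
#' @return 3D array with each dimension halved (rounded up).
#' @export
downsample_once <- function(volume_group) {
  stopifnot(length(dim(volume_group)) == 3)
  halve <- function(arr, axis) {
    n <- dim(arr)[axis]
    odd <- seq(1, n, by = 2)
    even <- seq_len(n)[seq_len(n) %% 2 == 0]
    ix <- function(idx) switch(axis,
      arr[idx, , , drop = FALSE],
      arr[, idx, , drop = FALSE],
      arr[, , idx, drop = FALSE])
    out <- ix(odd)
    if (length(even)) {
      paired <- seq_along(even)
      mean_part <- (ix(odd[paired]) + ix(even)) / 2
      switch(axis,
             out[paired, , ] <- mean_part,
             out[, paired, ] <- mean_part,
             out[, , paired] <- mean_part)
    }
    out
  }
  halve(halve(halve(volume_group * 1.0, 1), 2), 3)
}

.level_dims <- function(dims, level) {
  for (k in seq_len(level)) dims <- ceiling(dims / 2)
  as.integer(dims)
}

# Write one slice plane of one pyramid level, honoring the output layout.
.write_level_slice <- function(img, level_dir, z_index, layout,
                               multistack_dims, bits) {
  scale <- 2^bits - 1
  img <- round(img)
  if (layout == "single_stack") {
    .write_slice(img, file.path(level_dir, sprintf("%06d.tif",
                                                   z_index * .COORD_SCALE)),
                 bits)
  } else {
    nv <- nrow(img); nh <- ncol(img)
    v_starts <- seq(0, nv - 1, by = multistack_dims[1])
    h_starts <- seq(0, nh - 1, by = multistack_dims[2])
    for (v0 in v_starts) for (h0 in h_starts) {
      vi <- (v0 + 1):min(v0 + multistack_dims[1], nv)
      hi <- (h0 + 1):min(h0 + multistack_dims[2], nh)
      d1 <- sprintf("%06d", v0 * .COORD_SCALE)
      d2 <- paste0(d1, "_", sprintf("%06d", h0 * .COORD_SCALE))
      dir.create(file.path(level_dir, d1, d2), recursive = TRUE,
                 showWarnings = FALSE)
      .write_slice(img[vi, hi, drop = FALSE],
                   file.path(level_dir, d1, d2,
                             sprintf("%s_%06d.tif", d2,
                                     z_index * .COORD_SCALE)),
                   bits)
    }
  }
}

#' Fuse a placed volume and write its multiresolution pyramid
#'
#' Streams the volume in groups of `2^n_levels` slices: each group is fused
#' at full resolution, written as level 0, then repeatedly 2x2x2-mean
#' downsampled and written as levels 1..`n_levels`. Intensities are
#' accumulated in floating point and rounded half-to-even to the input bit
#' depth on write. Level directories are named `RES(VxHxD)` after their
#' dimensions. Optional ranges restrict fusion to a subvolume (preview).
#'
#' @param state A `stitch_state` at stage `placed`.
#' @param config A [merge_config()].
#' @param out_path Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param row_range,col_range,slice_range Optional half-open 0-based
#'   selection intervals.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `out_path`, invisibly. Side effect: one directory per level
#'   containing TIFF slices (single-stack) or a two-level tile hierarchy
#'   (multi-stack).
#' @export
write_pyramid <- function(state, config = merge_config(), out_path,
                          row_range = NULL, col_range = NULL,
                          slice_range = NULL, overwrite = FALSE) {
  .require_stage(state, "placed", "merge")
  if (dir.exists(out_path) && length(list.files(out_path)) > 0 && !overwrite)
    stop_io("output path exists and is not empty: ", out_path,
            " (use overwrite = TRUE)")
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  vol <- state$volume
  pl <- state$placements
  if (is.null(slice_range)) {
    d_lo <- min(pl$d)
    d_hi <- max(pl$d) + vol$n_slices_total
  } else {
    d_lo <- slice_range[1]; d_hi <- slice_range[2]
    if (d_lo >= d_hi) stop_usage("empty subvolume selection")
  }
  group_size <- 2L^config$n_levels
  n_z <- d_hi - d_lo

  # fuse one probe-free pass: footprint known from placements
  sel_pl <- pl
  if (!is.null(row_range))
    sel_pl <- sel_pl[sel_pl$row >= row_range[1] &
                       sel_pl$row < row_range[2], , drop = FALSE]
  if (!is.null(col_range))
    sel_pl <- sel_pl[sel_pl$col >= col_range[1] &
                       sel_pl$col < col_range[2], , drop = FALSE]
  if (nrow(sel_pl) == 0) stop_usage("empty subvolume selection")
  fp <- c(max(sel_pl$v + vol$tile_height_v) - min(sel_pl$v),
          max(sel_pl$h + vol$tile_width_h) - min(sel_pl$h))

  level_dirs <- character(config$n_levels + 1)
  for (k in 0:config$n_levels) {
    dims <- c(.level_dims(fp, k), .level_dims(n_z, k))
    level_dirs[k + 1] <- file.path(out_path, sprintf("RES(%dx%dx%d)",
                                                     dims[1], dims[2],
                                                     dims[3]))
    dir.create(level_dirs[k + 1], recursive = TRUE, showWarnings = FALSE)
  }

  group_starts <- seq(d_lo, d_hi - 1L, by = group_size)
  for (g0 in group_starts) {
    zs <- g0:min(g0 + group_size - 1L, d_hi - 1L)
    slices <- fuse_slice_group(state, zs, config, row_range, col_range)
    arr <- array(0, dim = c(fp[1], fp[2], length(zs)))
    for (i in seq_along(zs)) arr[, , i] <- slices[[i]]
    for (k in 0:config$n_levels) {
      if (k > 0) arr <- downsample_once(arr)
      z_base <- (g0 - d_lo) %/% (2L^k)
      for (i in seq_len(dim(arr)[3]))
        .write_level_slice(matrix(arr[, , i], dim(arr)[1], dim(arr)[2]),
                           level_dirs[k + 1], z_base + i - 1L,
                           config$output_layout, config$multistack_dims,
                           vol$bits)
    }
  }
  invisible(out_path)
}
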