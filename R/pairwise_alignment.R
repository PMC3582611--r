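# Pairwise displacement estimation by NCC of maximum intensity projections.
#
# Each adjacent tile pair is aligned substack by substack: the nominally
# overlapping region of both tiles is condensed into three MIPs (along V, H
# and D), a 2D NCC map over a (2*delta_search+1)^2 search window is computed
# for each pair of homologous MIPs, and each map's peak contributes one
# candidate displacement to each of the two directions its axes resolve --
# six candidates in all, two per direction. Per direction the candidate
# with the higher reliability (peak value discounted by peak width) wins.
#
# Offsets are signed corrections relative to the nominal stage alignment:
# the true displacement of tile b relative to tile a is the nominal
# displacement plus the offset.

#' Alignment configuration
#'
#' @param n_slices Substack depth along D; the volume is processed one layer
#'   of at most `n_slices` slices at a time. Typical values 100-200.
#' @param delta_search Search half-width in voxels; NCC maps have side
#'   `2 * delta_search + 1`. Must cover the largest expected stage error.
#' @param width_fraction Fraction of the peak value used to measure the
#'   peak width (contiguous run through the peak at or above
#'   `width_fraction * peak_value`).
#' @return An `align_config` list.
#' @export
align_config <- function(n_slices = 100, delta_search = 16,
                         width_fraction = 0.75) {
  stopifnot(n_slices >= 1, delta_search >= 1,
            width_fraction > 0, width_fraction < 1)
  structure(list(n_slices = as.integer(n_slices),
                 delta_search = as.integer(delta_search),
                 width_fraction = width_fraction), class = "align_config")
}

#' Maximum intensity projection
#'
#' Element-wise maximum of a 3D array along one of the V, H, D axes. Output
#' axes keep the (V, H, D) order of the remaining two.
#'
#' @param arr 3D array in (V, H, D) order.
#' @param axis One of `"V"`, `"H"`, `"D"`.
#' @return 2D matrix.
#' @export
mip <- function(arr, axis = c("V", "H", "D")) {
  axis <- match.arg(axis)
  stopifnot(length(dim(arr)) == 3, all(dim(arr) >= 1))
  d <- dim(arr)
  switch(axis,
    D = Reduce(pmax, lapply(seq_len(d[3]), function(k) arr[, , k])),
    V = {
      out <- matrix(arr[1, , ], d[2], d[3])
      for (i in seq_len(d[1])[-1]) out <- pmax(out, matrix(arr[i, , ],
                                                           d[2], d[3]))
      out
    },
    H = {
      out <- matrix(arr[, 1, ], d[1], d[3])
      for (j in seq_len(d[2])[-1]) out <- pmax(out, matrix(arr[, j, ],
                                                           d[1], d[3]))
      out
    })
}

#' Normalized cross-correlation map over a shift window
#'
#' For every integer shift `(u, v)` with `|u|, |v| <= delta_search`,
#' computes the zero-mean NCC between `img_a` and `img_b` shifted by
#' `(u, v)`, on the intersection of their supports after the shift (the
#' score at `(u, v)` correlates `a[i, j]` with `b[i + u, j + v]`). Means and
#' variances are taken over the intersection; shifts where either operand
#' has zero variance score 0. Two entirely constant images yield an
#' all-zero map flagged `degenerate` rather than an error.
#'
#' @param img_a,img_b Numeric matrices of identical shape, both sides
#'   strictly larger than `2 * delta_search`.
#' @param delta_search Search half-width.
#' @return An `ncc_map`: list with `values` (the
#'   `(2*delta_search+1)` square score matrix), `delta_search` and
#'   `degenerate`.
#' @export
ncc_map <- function(img_a, img_b, delta_search) {
  stopifnot(is.matrix(img_a), is.matrix(img_b),
            identical(dim(img_a), dim(img_b)))
  ds <- as.integer(delta_search)
  m <- nrow(img_a); n <- ncol(img_a)
  if (m <= 2 * ds || n <= 2 * ds)
    stop_usage("images (", m, " x ", n, ") must be strictly larger than ",
               "2 * delta_search = ", 2 * ds, " in both axes")
  side <- 2L * ds + 1L
  vals <- matrix(0, side, side)
  degenerate_a <- stats::var(as.vector(img_a)) == 0
  degenerate_b <- stats::var(as.vector(img_b)) == 0
  if (!(degenerate_a && degenerate_b)) {
    a <- img_a * 1.0; b <- img_b * 1.0
    for (u in -ds:ds) {
      ia0 <- max(1L, 1L - u); ia1 <- min(m, m - u)
      for (v in -ds:ds) {
        ja0 <- max(1L, 1L - v); ja1 <- min(n, n - v)
        asub <- a[ia0:ia1, ja0:ja1, drop = FALSE]
        bsub <- b[(ia0 + u):(ia1 + u), (ja0 + v):(ja1 + v), drop = FALSE]
        am <- asub - mean(asub)
        bm <- bsub - mean(bsub)
        den <- sqrt(sum(am * am) * sum(bm * bm))
        vals[u + ds + 1L, v + ds + 1L] <-
          if (den == 0) 0 else sum(am * bm) / den
      }
    }
  }
  structure(list(values = vals, delta_search = ds,
                 degenerate = degenerate_a && degenerate_b),
            class = "ncc_map")
}

#' Peak location, value and widths of an NCC map
#'
#' The peak is the maximum of the map; ties are broken toward the smallest
#' Euclidean shift magnitude (nominal coordinates are trusted to within a
#' small drift), then lexicographically. The width along each map axis is
#' the number of contiguous cells through the peak whose value is at least
#' `width_fraction * peak_value`.
#'
#' @param map An [ncc_map()].
#' @param width_fraction Peak-width threshold fraction.
#' @return List with `peak_shift` (integer `(u, v)`), `peak_value` and
#'   `widths` (length 2, along the map's two axes).
#' @export
peak_and_width <- function(map, width_fraction = 0.75) {
  stopifnot(inherits(map, "ncc_map"))
  vals <- map$values
  ds <- map$delta_search
  pv <- max(vals)
  cand <- which(vals == pv, arr.ind = TRUE)
  shifts <- cand - (ds + 1L) # rows: (u, v)
  ord <- order(shifts[, 1]^2 + shifts[, 2]^2, shifts[, 1], shifts[, 2])
  peak <- shifts[ord[1], ]
  pi_ <- peak[1] + ds + 1L
  pj <- peak[2] + ds + 1L
  thr <- width_fraction * pv
  run <- function(line, at) {
    lo <- at
    while (lo > 1 && line[lo - 1] >= thr) lo <- lo - 1
    hi <- at
    while (hi < length(line) && line[hi + 1] >= thr) hi <- hi + 1
    hi - lo + 1L
  }
  widths <- c(run(vals[, pj], pi_), run(vals[pi_, ], pj))
  list(peak_shift = as.integer(peak), peak_value = pv,
       widths = as.integer(widths))
}

#' Reliability of a candidate displacement
#'
#' Combines the NCC peak value (higher is better) and the peak width
#' (narrower is better) into one score in `[0, 1]`:
#' `max(0, peak_value) * (map_side - width) / (map_side - 1)`. A
#' non-positive peak scores 0; a width of 1 returns the peak value
#' unchanged; the score is non-decreasing in the peak value and
#' non-increasing in the width.
#'
#' @param peak_value NCC score at the peak.
#' @param width Peak width in pixels, in `[1, map_side]`.
#' @param map_side Side of the NCC map (`2 * delta_search + 1`).
#' @return Scalar in `[0, 1]`.
#' @export
reliability <- function(peak_value, width, map_side) {
  stopifnot(width >= 1, width <= map_side, map_side >= 2)
  max(0, min(1, peak_value)) * (map_side - width) / (map_side - 1)
}

#' Nominal overlap regions of an adjacent tile pair
#'
#' Uses the nominal stage coordinates to locate the overlapping region of
#' two adjacent tiles, expanded by `delta_search` along the two
#' non-adjacency axes where the tile extents permit, so that every shift in
#' the search window compares valid data. Both ROIs have identical shape.
#'
#' @param volume A `tiled_volume`.
#' @param pair List with `a_row`, `a_col`, `b_row`, `b_col`, `axis` (the
#'   adjacency axis, `"V"` or `"H"`).
#' @param delta_search Search half-width used for the expansion.
#' @return List with `roi_a` and `roi_b`, each a list of half-open 0-based
#'   local intervals `v`, `h`, `d` (`c(lo, hi)`).
#' @export
compute_overlap_rois <- function(volume, pair, delta_search = 0) {
  a <- vol_tile(volume, pair$a_row, pair$a_col)
  b <- vol_tile(volume, pair$b_row, pair$b_col)
  ext <- c(V = volume$tile_height_v, H = volume$tile_width_h,
           D = volume$n_slices_total)
  nom <- list(a = c(V = a$nominal_v, H = a$nominal_h, D = a$nominal_d),
              b = c(V = b$nominal_v, H = b$nominal_h, D = b$nominal_d))
  roi_a <- list(); roi_b <- list()
  for (ax in .AXES) {
    lo <- max(nom$a[ax], nom$b[ax])
    hi <- min(nom$a[ax] + ext[ax], nom$b[ax] + ext[ax])
    if (ax == pair$axis) {
      if (hi <= lo)
        stop_usage("no overlap between tiles (", pair$a_row, ",", pair$a_col,
                   ") and (", pair$b_row, ",", pair$b_col, ") along ", ax)
    } else {
      lo <- max(lo - delta_search, nom$a[ax], nom$b[ax])
      hi <- min(hi + delta_search, nom$a[ax] + ext[ax], nom$b[ax] + ext[ax])
    }
    roi_a[[tolower(ax)]] <- c(lo, hi) - nom$a[ax]
    roi_b[[tolower(ax)]] <- c(lo, hi) - nom$b[ax]
  }
  list(roi_a = roi_a, roi_b = roi_b)
}

# Crop a loaded substack (local slices [sub_z0, sub_z1)) to an ROI box,
# restricting the ROI's D interval to the substack.
.crop_roi <- function(arr, roi, sub_z0) {
  arr[(roi$v[1] + 1):roi$v[2],
      (roi$h[1] + 1):roi$h[2],
      (roi$d[1] - sub_z0 + 1):(roi$d[2] - sub_z0), drop = FALSE]
}

#' Align one pair of homologous substacks
#'
#' Computes the three MIPs of each overlap ROI, the three NCC maps, and the
#' six candidate displacements (two per direction): the map from the MIP
#' along D resolves V and H, along V resolves H and D, along H resolves V
#' and D. Each candidate's reliability uses the peak width along the map
#' axis corresponding to the candidate's direction. Per direction the more
#' reliable candidate is kept. A fully constant overlap yields offset 0,
#' reliability 0 per direction rather than an error.
#'
#' @param sub_a,sub_b 3D arrays: the overlap ROIs of the two tiles (same
#'   shape, same D interval).
#' @param config An [align_config()].
#' @return List with `candidates` (all six, each with `direction`,
#'   `offset`, `peak_value`, `width`, `reliability`), `offset` and
#'   `reliability` (named per-direction best).
#' @export
align_substack_pair <- function(sub_a, sub_b, config = align_config()) {
  stopifnot(identical(dim(sub_a), dim(sub_b)))
  ds <- config$delta_search
  side <- 2L * ds + 1L
  # map axis -> the two directions its NCC map resolves, in map-axis order
  plan <- list(D = c("V", "H"), V = c("H", "D"), H = c("V", "D"))
  candidates <- list()
  for (proj in names(plan)) {
    dirs <- plan[[proj]]
    ma <- mip(sub_a, proj)
    mb <- mip(sub_b, proj)
    if (nrow(ma) <= 2 * ds || ncol(ma) <= 2 * ds) {
      # overlap too thin to search: contribute unreliable candidates
      for (k in 1:2)
        candidates[[length(candidates) + 1L]] <-
          list(direction = dirs[k], offset = 0L, peak_value = 0,
               width = side, reliability = 0)
      next
    }
    map <- ncc_map(ma, mb, ds)
    pk <- peak_and_width(map, config$width_fraction)
    for (k in 1:2) {
      rel <- if (map$degenerate) 0 else
        reliability(pk$peak_value, pk$widths[k], side)
      candidates[[length(candidates) + 1L]] <- list(
        direction = dirs[k],
        offset = if (map$degenerate) 0L else -pk$peak_shift[k],
        peak_value = pk$peak_value, width = pk$widths[k],
        reliability = rel)
    }
  }
  offset <- stats::setNames(integer(3), .AXES)
  reliab <- stats::setNames(numeric(3), .AXES)
  for (d in .AXES) {
    cs <- Filter(function(x) x$direction == d, candidates)
    best <- cs[[which.max(vapply(cs, `[[`, numeric(1), "reliability"))]]
    offset[d] <- best$offset
    reliab[d] <- best$reliability
  }
  list(candidates = candidates, offset = offset, reliability = reliab)
}

# Split [z_lo, z_hi) into layers of at most n_slices.
.layers <- function(z_lo, z_hi, n_slices) {
  starts <- seq(z_lo, z_hi - 1L, by = n_slices)
  lapply(starts, function(s) c(s, min(s + n_slices, z_hi)))
}

#' Compute all pairwise displacements of a volume
#'
#' Runs substack-pair alignment for every adjacent tile pair and every D
#' layer of at most `n_slices` slices, streaming tiles so that at no
#' instant more than `min(n_rows, n_cols) + 1` substacks are resident:
#' tiles are traversed row-wise when `n_rows >= n_cols` (column-wise
#' otherwise) and each substack is released as soon as its South and East
#' pairs are done. Every slice is read exactly once per step. Optional
#' ranges restrict the computation to a subvolume (preview).
#'
#' @param volume A `tiled_volume`.
#' @param config An [align_config()].
#' @param row_range,col_range 0-based half-open `c(lo, hi)` tile index
#'   ranges (default: all).
#' @param slice_range 0-based half-open slice range along D (default: all).
#' @return A `stitch_state` at stage `displacements_computed`, holding one
#'   per-substack displacement record per pair and layer.
#' @export
align_volume <- function(volume, config = align_config(),
                         row_range = NULL, col_range = NULL,
                         slice_range = NULL) {
  stopifnot(inherits(volume, "tiled_volume"))
  if (is.null(row_range)) row_range <- c(0L, volume$n_rows)
  if (is.null(col_range)) col_range <- c(0L, volume$n_cols)
  if (is.null(slice_range)) slice_range <- c(0L, volume$n_slices_total)
  if (row_range[1] >= row_range[2] || col_range[1] >= col_range[2] ||
      slice_range[1] >= slice_range[2])
    stop_usage("empty subvolume selection")
  stopifnot(row_range[1] >= 0, row_range[2] <= volume$n_rows,
            col_range[1] >= 0, col_range[2] <= volume$n_cols,
            slice_range[1] >= 0, slice_range[2] <= volume$n_slices_total)

  rows <- row_range[1]:(row_range[2] - 1L)
  cols <- col_range[1]:(col_range[2] - 1L)
  sel_rows <- length(rows); sel_cols <- length(cols)
  row_wise <- sel_rows >= sel_cols
  layers <- .layers(slice_range[1], slice_range[2], config$n_slices)

  state <- .new_state("displacements_computed", volume)
  pair_index <- new.env(parent = emptyenv())
  for (i in seq_along(state$pairs)) {
    p <- state$pairs[[i]]
    assign(paste(p$a_row, p$a_col, p$b_row, p$b_col, sep = "_"), i,
           envir = pair_index)
  }
  for (layer in layers) {
    resident <- new.env(parent = emptyenv())
    key <- function(r, c) paste(r, c, sep = "_")
    load_tile <- function(r, c) {
      arr <- load_substack(volume,
                           substack_ref(volume, r, c, layer[1], layer[2]))
      assign(key(r, c), arr, envir = resident)
      .substack_loaded()
      arr
    }
    release_tile <- function(r, c) {
      if (exists(key(r, c), envir = resident)) {
        rm(list = key(r, c), envir = resident)
        .substack_released()
      }
    }
    do_pair <- function(ar, ac, br, bc) {
      i <- get(paste(ar, ac, br, bc, sep = "_"), envir = pair_index)
      p <- state$pairs[[i]]
      rois <- compute_overlap_rois(volume, p, config$delta_search)
      # restrict D to this layer (local slice indices; adjacent tiles share
      # the layer interval)
      da <- c(max(rois$roi_a$d[1], layer[1]), min(rois$roi_a$d[2], layer[2]))
      db <- c(max(rois$roi_b$d[1], layer[1]), min(rois$roi_b$d[2], layer[2]))
      if (da[1] >= da[2] || db[1] >= db[2]) return(invisible(NULL))
      ra <- rois$roi_a; ra$d <- da
      rb <- rois$roi_b; rb$d <- db
      nz <- min(da[2] - da[1], db[2] - db[1])
      ra$d[2] <- ra$d[1] + nz
      rb$d[2] <- rb$d[1] + nz
      sub_a <- .crop_roi(get(key(ar, ac), envir = resident), ra, layer[1])
      sub_b <- .crop_roi(get(key(br, bc), envir = resident), rb, layer[1])
      res <- align_substack_pair(sub_a, sub_b, config)
      p$layers[[length(p$layers) + 1L]] <-
        list(z0 = layer[1], z1 = layer[2],
             offset = res$offset, reliability = res$reliability)
      state$pairs[[i]] <<- p
    }
    # traverse the selected grid; (p, q) -> (row, col) depends on direction
    outer_idx <- if (row_wise) rows else cols
    inner_idx <- if (row_wise) cols else rows
    rc <- function(p, q) if (row_wise) c(p, q) else c(q, p)
    for (p_i in seq_along(outer_idx)) {
      for (q_i in seq_along(inner_idx)) {
        cur <- rc(outer_idx[p_i], inner_idx[q_i])
        load_tile(cur[1], cur[2])
        # pair with the previously-loaded neighbor along the inner axis
        if (q_i > 1) {
          prev <- rc(outer_idx[p_i], inner_idx[q_i - 1])
          do_pair(prev[1], prev[2], cur[1], cur[2])
        }
        # pair with the neighbor from the previous outer line, then release
        # it: both of its forward pairs are now done
        if (p_i > 1) {
          up <- rc(outer_idx[p_i - 1], inner_idx[q_i])
          do_pair(up[1], up[2], cur[1], cur[2])
          release_tile(up[1], up[2])
        }
      }
      # a line's last tile has no further forward pairs on the inner axis;
      # tiles of the final outer line are released when the layer ends
    }
    for (k in ls(resident)) {
      rm(list = k, envir = resident)
      .substack_released()
    }
  }
  state
}
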