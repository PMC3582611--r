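# Tiled-volume model: two-level directory hierarchy of TIFF slice stacks.
#
# Naming dialect: first-level directories encode the V stage position,
# second-level directories V_H, slice files V_H_D, each coordinate a
# zero-padded 6-digit integer in tenths of micrometre so lexicographic
# order equals spatial order. The physical unit is a convention of this
# package, configurable through `voxel_size` at import.

.COORD_SCALE <- 10 # tenths of a micrometre per micrometre

.pos_to_name <- function(voxels, voxel_size_um) {
  sprintf("%06d", as.integer(round(voxels * voxel_size_um * .COORD_SCALE)))
}

.name_to_pos <- function(tenths, voxel_size_um) {
  as.integer(round(as.numeric(tenths) / .COORD_SCALE / voxel_size_um))
}

#' Import a tiled-volume directory hierarchy
#'
#' Scans a two-level hierarchy of tile directories and builds the in-memory
#' description of the tile matrix: grid shape, tile dimensions, per-tile
#' nominal stage coordinates (converted from the physical units embedded in
#' directory names to voxels) and the ordered slice file list of every tile.
#' The grid must be complete and all tiles must have identical dimensions.
#'
#' @param root_path Directory containing the first-level (V) directories.
#' @param voxel_size Numeric length-3 vector, micrometres per voxel along
#'   (V, H, D).
#' @return A `tiled_volume` object: a list with the grid shape (`n_rows`,
#'   `n_cols`), tile dimensions (`tile_height_v`, `tile_width_h`,
#'   `n_slices_total`), `voxel_size`, `bits` (TIFF bit depth), `root_path`
#'   and `tiles`, a row-major list of per-tile records (0-based `row`,
#'   `col`, nominal voxel coordinates, relative `slice_paths`,
#'   `stitchable`).
#' @export
import_volume <- function(root_path, voxel_size = c(1, 1, 1)) {
  if (!dir.exists(root_path)) stop_io("root path does not exist: ", root_path)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))

  lvl1 <- sort(list.dirs(root_path, full.names = FALSE, recursive = FALSE))
  if (length(lvl1) == 0) stop_io("no tile directories under ", root_path)
  bad <- lvl1[!grepl("^[0-9]{6}$", lvl1)]
  if (length(bad))
    stop("unparsable first-level directory name: ",
         file.path(root_path, bad[1]))

  tiles <- list()
  for (d1 in lvl1) {
    lvl2 <- sort(list.dirs(file.path(root_path, d1),
                           full.names = FALSE, recursive = FALSE))
    bad <- lvl2[!grepl("^[0-9]{6}_[0-9]{6}$", lvl2)]
    if (length(bad))
      stop("unparsable second-level directory name: ",
           file.path(root_path, d1, bad[1]))
    for (d2 in lvl2) {
      parts <- strsplit(d2, "_", fixed = TRUE)[[1]]
      if (parts[1] != d1)
        stop("unparsable second-level directory name (V mismatch): ",
             file.path(root_path, d1, d2))
      files <- sort(list.files(file.path(root_path, d1, d2),
                               pattern = "\\.tiff?$", full.names = FALSE))
      if (length(files) == 0)
        stop_io("tile directory has no slice files: ",
                file.path(root_path, d1, d2))
      badf <- files[!grepl("^[0-9]{6}_[0-9]{6}_[0-9]{6}\\.tiff?$", files)]
      if (length(badf))
        stop("unparsable slice file name: ",
             file.path(root_path, d1, d2, badf[1]))
      d_tenths <- sub("^[0-9]{6}_[0-9]{6}_([0-9]{6})\\..*$", "\\1", files[1])
      tiles[[length(tiles) + 1L]] <- list(
        v_tenths = as.integer(d1),
        h_tenths = as.integer(parts[2]),
        d_tenths = as.integer(d_tenths),
        slice_paths = file.path(d1, d2, files)
      )
    }
  }

  v_vals <- sort(unique(vapply(tiles, `[[`, integer(1), "v_tenths")))
  h_vals <- sort(unique(vapply(tiles, `[[`, integer(1), "h_tenths")))
  n_rows <- length(v_vals)
  n_cols <- length(h_vals)

  grid <- vector("list", n_rows * n_cols)
  for (t in tiles) {
    r <- match(t$v_tenths, v_vals) - 1L
    c <- match(t$h_tenths, h_vals) - 1L
    grid[[r * n_cols + c + 1L]] <- t
  }
  for (r in seq_len(n_rows) - 1L) for (c in seq_len(n_cols) - 1L) {
    if (is.null(grid[[r * n_cols + c + 1L]]))
      stop("incomplete grid: missing tile at (row ", r, ", col ", c, ")")
  }

  n_slices <- length(grid[[1]]$slice_paths)
  for (i in seq_along(grid)) {
    if (length(grid[[i]]$slice_paths) != n_slices) {
      t <- grid[[i]]
      stop("inconsistent slice count: tile at (row ",
           (i - 1L) %/% n_cols, ", col ", (i - 1L) %% n_cols, ") has ",
           length(t$slice_paths), " slices, expected ", n_slices)
    }
  }

  first <- file.path(root_path, grid[[1]]$slice_paths[1])
  img <- tryCatch(tiff::readTIFF(first, as.is = TRUE, info = TRUE),
                  error = function(e) stop_io("cannot read slice file ",
                                              first, ": ", conditionMessage(e)))
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L

  vol_tiles <- vector("list", n_rows * n_cols)
  for (r in seq_len(n_rows) - 1L) for (c in seq_len(n_cols) - 1L) {
    t <- grid[[r * n_cols + c + 1L]]
    vol_tiles[[r * n_cols + c + 1L]] <- list(
      row = r, col = c,
      nominal_v = .name_to_pos(t$v_tenths, voxel_size[1]),
      nominal_h = .name_to_pos(t$h_tenths, voxel_size[2]),
      nominal_d = .name_to_pos(t$d_tenths, voxel_size[3]),
      slice_paths = t$slice_paths,
      stitchable = TRUE
    )
  }

  structure(list(
    n_rows = n_rows, n_cols = n_cols,
    tile_height_v = nrow(img), tile_width_h = ncol(img),
    n_slices_total = n_slices,
    voxel_size = as.numeric(voxel_size),
    bits = as.integer(bits),
    root_path = normalizePath(root_path),
    tiles = vol_tiles
  ), class = "tiled_volume")
}

#' @export
print.tiled_volume <- function(x, ...) {
  cat(sprintf(
    "tiled_volume: %d x %d tiles of %d x %d x %d voxels (%d-bit)\n",
    x$n_rows, x$n_cols, x$tile_height_v, x$tile_width_h,
    x$n_slices_total, x$bits))
  cat("  root:", x$root_path, "\n")
  invisible(x)
}

#' Access one tile of a tiled volume
#'
#' @param volume A `tiled_volume`.
#' @param row,col 0-based grid indices.
#' @return The tile record (see [import_volume()]).
#' @export
vol_tile <- function(volume, row, col) {
  stopifnot(row >= 0, row < volume$n_rows, col >= 0, col < volume$n_cols)
  volume$tiles[[row * volume$n_cols + col + 1L]]
}

#' Reference a substack of a tile
#'
#' A substack is a contiguous run of slices of one tile along D, the unit
#' of pairwise alignment. The D interval is half-open, `[z0, z1)`.
#'
#' @inheritParams vol_tile
#' @param z0,z1 0-based half-open slice interval.
#' @return A `substack_ref` list.
#' @export
substack_ref <- function(volume, row, col, z0, z1) {
  if (!(z0 >= 0 && z0 < z1 && z1 <= volume$n_slices_total))
    stop_usage("invalid substack interval [", z0, ", ", z1,
               "): slices per tile = ", volume$n_slices_total)
  structure(list(row = row, col = col, z0 = as.integer(z0),
                 z1 = as.integer(z1)), class = "substack_ref")
}

.read_slice <- function(path) {
  if (!file.exists(path)) stop_io("slice file not found: ", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop_io("cannot read slice file ",
                                              path, ": ",
                                              conditionMessage(e)))
  .count_read(path)
  img
}

#' Load a substack into memory
#'
#' Reads the referenced slice files and stacks them into a 3D array in
#' (V, H, D) order. Intensities are preserved bit-exactly from the files.
#'
#' @param volume A `tiled_volume`.
#' @param ref A [substack_ref()].
#' @return Integer array of dimension
#'   `(tile_height_v, tile_width_h, z1 - z0)`.
#' @export
load_substack <- function(volume, ref) {
  stopifnot(inherits(ref, "substack_ref"))
  if (ref$z1 > volume$n_slices_total)
    stop_usage("substack interval exceeds tile depth")
  tile <- vol_tile(volume, ref$row, ref$col)
  nz <- ref$z1 - ref$z0
  arr <- array(0L, dim = c(volume$tile_height_v, volume$tile_width_h, nz))
  for (k in seq_len(nz)) {
    path <- file.path(volume$root_path, tile$slice_paths[ref$z0 + k])
    img <- .read_slice(path)
    if (nrow(img) != volume$tile_height_v || ncol(img) != volume$tile_width_h)
      stop_io("slice dimension mismatch in ", path)
    arr[, , k] <- img
  }
  arr
}

# Write a (V,H) integer matrix as a grayscale TIFF slice.
.write_slice <- function(img, path, bits) {
  scale <- 2^bits - 1
  img <- pmin(pmax(img, 0), scale)
  tiff::writeTIFF(img / scale, path, bits.per.sample = bits,
                  compression = "none")
  invisible(path)
}

# Enumerate the adjacent pairs of the grid in canonical order: row-major
# over tiles, each tile contributing its East (H axis) then South (V axis)
# pair. n_rows*(n_cols-1) + (n_rows-1)*n_cols pairs in total.
.enumerate_pairs <- function(n_rows, n_cols) {
  pairs <- list()
  for (r in seq_len(n_rows) - 1L) for (c in seq_len(n_cols) - 1L) {
    if (c + 1L < n_cols)
      pairs[[length(pairs) + 1L]] <-
        list(a_row = r, a_col = c, b_row = r, b_col = c + 1L, axis = "H")
    if (r + 1L < n_rows)
      pairs[[length(pairs) + 1L]] <-
        list(a_row = r, a_col = c, b_row = r + 1L, b_col = c, axis = "V")
  }
  pairs
}
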