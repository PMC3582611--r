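# Synthetic tiled acquisitions with known ground truth.
#
# The generator emulates what stitching actually sees: a structured volume
# (filaments + blobs on a dark background, possibly with an information-free
# region) cut into an R x C grid of overlapping tiles, each cropped at its
# nominal grid position plus an unknown integer stage jitter, with
# independent additive noise per tile so that overlap regions are similar
# but not identical, as in real repeated acquisitions.

.BACKGROUND <- 20
.AMPLITUDE <- 180

#' Generate a structured phantom volume
#'
#' Produces a deterministic 3D intensity array containing random curvilinear
#' filaments and Gaussian blobs on a dark background. An optional contiguous
#' fraction of the volume (a slab along H at the high-H end) is left
#' background-only, mimicking acquisitions where selectively labeled
#' specimens leave parts of the imaged volume without information content.
#'
#' @param shape_vhd Integer length-3, array dimensions along (V, H, D).
#' @param content_density Expected number of structures per 10^4 voxels of
#'   content region (default 0.5). 0 gives a constant background volume.
#' @param empty_fraction Fraction in `[0, 1)` of the volume kept
#'   background-only.
#' @param seed Integer seed; the same seed always yields the same phantom.
#' @return Integer array of dimension `shape_vhd`, values in `[0, 255]`.
#' @export
make_phantom <- function(shape_vhd, content_density = 0.5,
                         empty_fraction = 0, seed = 1) {
  stopifnot(length(shape_vhd) == 3, all(shape_vhd >= 1),
            empty_fraction >= 0, empty_fraction < 1,
            content_density >= 0)
  nv <- shape_vhd[1]; nh <- shape_vhd[2]; nd <- shape_vhd[3]
  vol <- array(.BACKGROUND, dim = c(nv, nh, nd))
  # content restricted to H < h_max: the slab [h_max, nh) stays empty
  h_max <- max(1, floor(nh * (1 - empty_fraction)))
  n_struct <- max(if (content_density > 0) 1L else 0L,
                  round(content_density * nv * h_max * nd / 1e4))
  if (n_struct == 0) return(vol)

  with_seed(seed, {
    for (s in seq_len(n_struct)) {
      if (s %% 2 == 1) {
        # curvilinear filament: a smoothed 3D random walk of bright voxels
        len <- sample(20:60, 1)
        pos <- c(runif(1, 1, nv), runif(1, 1, h_max), runif(1, 1, nd))
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        amp <- .AMPLITUDE * runif(1, 0.6, 1)
        for (step in seq_len(len)) {
          dir <- dir + stats::rnorm(3, sd = 0.3)
          dir <- dir / sqrt(sum(dir^2))
          pos <- pos + dir
          i <- round(pos)
          if (i[1] < 1 || i[1] > nv || i[2] < 1 || i[2] > h_max ||
              i[3] < 1 || i[3] > nd) break
          vol[i[1], i[2], i[3]] <- .BACKGROUND + amp
          # 1-voxel halo keeps filaments visible in projections
          for (dd in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
            j <- i + dd
            if (all(j >= 1) && j[1] <= nv && j[2] <= h_max && j[3] <= nd)
              vol[j[1], j[2], j[3]] <-
                max(vol[j[1], j[2], j[3]], .BACKGROUND + 0.5 * amp)
          }
        }
      } else {
        # Gaussian blob
        ctr <- c(runif(1, 1, nv), runif(1, 1, h_max), runif(1, 1, nd))
        sg <- runif(1, 1.5, 4)
        amp <- .AMPLITUDE * runif(1, 0.5, 1)
        rad <- ceiling(2.5 * sg)
        iv <- max(1, floor(ctr[1] - rad)):min(nv, ceiling(ctr[1] + rad))
        ih <- max(1, floor(ctr[2] - rad)):min(h_max, ceiling(ctr[2] + rad))
        id <- max(1, floor(ctr[3] - rad)):min(nd, ceiling(ctr[3] + rad))
        if (!length(iv) || !length(ih) || !length(id)) next
        gv <- exp(-(iv - ctr[1])^2 / (2 * sg^2))
        gh <- exp(-(ih - ctr[2])^2 / (2 * sg^2))
        gd <- exp(-(id - ctr[3])^2 / (2 * sg^2))
        bump <- amp * outer(outer(gv, gh), gd)
        dim(bump) <- c(length(iv), length(ih), length(id))
        vol[iv, ih, id] <- pmax(vol[iv, ih, id], .BACKGROUND + bump)
      }
    }
  })
  array(as.integer(pmin(round(vol), 255L)), dim = dim(vol))
}

#' Cut a phantom into an overlapping, jittered, noisy tile hierarchy
#'
#' Writes a two-level TIFF hierarchy that [import_volume()] can read.
#' Nominal coordinates encode the ideal jitter-free grid; the actual crop of
#' each tile is taken at nominal + jitter, where the per-tile jitter is
#' drawn uniformly on integers in `[-jitter_max, jitter_max]` per direction
#' (tile (0,0) is the anchor and gets zero jitter). Independent Gaussian
#' noise is added per tile and clipped to the 8-bit range, so the two copies
#' of an overlap region differ, as in real acquisitions. All crops are
#' offset by a `jitter_max` margin inside the phantom so jitter never falls
#' outside it.
#'
#' @param phantom 3D integer array from [make_phantom()].
#' @param n_rows,n_cols Grid shape.
#' @param tile_shape Integer length-3 tile dimensions (V, H, D).
#' @param overlap_vh Integer length-2 nominal overlap in voxels along
#'   (V, H); must be at least `2 * jitter_max + 1`.
#' @param jitter_max Maximum absolute per-direction stage jitter in voxels.
#' @param noise_sigma Standard deviation of the per-tile additive noise.
#' @param seed Integer seed for jitter and noise.
#' @param out_path Directory to create the hierarchy in (must not contain
#'   one already).
#' @param voxel_size Micrometres per voxel (V, H, D), used for the
#'   coordinate encoding in names.
#' @return A list with `volume` (the imported `tiled_volume`) and
#'   `ground_truth`, a data frame with one row per tile: grid indices,
#'   nominal position, jitter and true position (phantom coordinates,
#'   margin included). The ground truth is also written as
#'   `ground_truth.csv` inside `out_path`.
#' @export
tile_phantom <- function(phantom, n_rows, n_cols, tile_shape, overlap_vh,
                         jitter_max = 0, noise_sigma = 0, seed = 1,
                         out_path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(tile_shape) == 3, length(overlap_vh) == 2,
            n_rows >= 1, n_cols >= 1, jitter_max >= 0, noise_sigma >= 0)
  if (jitter_max > 0 && any(overlap_vh < 2 * jitter_max + 1))
    stop_usage("overlap must be at least 2*jitter_max + 1 so that jittered ",
               "tiles still overlap")
  step_v <- tile_shape[1] - overlap_vh[1]
  step_h <- tile_shape[2] - overlap_vh[2]
  if (step_v <= 0 || step_h <= 0)
    stop_usage("overlap must be smaller than the tile extent")
  need <- c((n_rows - 1) * step_v + tile_shape[1] + 2 * jitter_max,
            (n_cols - 1) * step_h + tile_shape[2] + 2 * jitter_max,
            tile_shape[3] + 2 * jitter_max)
  if (any(dim(phantom) < need))
    stop_usage("phantom too small for this grid: need at least (",
               paste(need, collapse = ", "), "), have (",
               paste(dim(phantom), collapse = ", "), ")")
  if (dir.exists(out_path) && length(list.files(out_path)) > 0)
    stop_io("output path exists and is not empty: ", out_path)
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)

  gt <- with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_rows) - 1L) for (c in seq_len(n_cols) - 1L) {
      nominal <- c(r * step_v, c * step_h, 0L)
      jit <- if (r == 0L && c == 0L) c(0L, 0L, 0L) else
        as.integer(sample(seq(-jitter_max, jitter_max), 3, replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        row = r, col = c,
        nominal_v = nominal[1], nominal_h = nominal[2], nominal_d = nominal[3],
        jitter_v = jit[1], jitter_h = jit[2], jitter_d = jit[3],
        true_v = nominal[1] + jit[1] + jitter_max,
        true_h = nominal[2] + jit[2] + jitter_max,
        true_d = nominal[3] + jit[3] + jitter_max
      )
    }
    gt <- do.call(rbind, rows)

    for (i in seq_len(nrow(gt))) {
      g <- gt[i, ]
      crop <- phantom[g$true_v + seq_len(tile_shape[1]),
                      g$true_h + seq_len(tile_shape[2]),
                      g$true_d + seq_len(tile_shape[3]), drop = FALSE]
      if (noise_sigma > 0) {
        crop <- crop + stats::rnorm(length(crop), sd = noise_sigma)
        crop <- pmin(pmax(round(crop), 0), 255)
      }
      d1 <- .pos_to_name(g$nominal_v, voxel_size[1])
      d2 <- paste0(d1, "_", .pos_to_name(g$nominal_h, voxel_size[2]))
      dir.create(file.path(out_path, d1, d2), recursive = TRUE,
                 showWarnings = FALSE)
      for (k in seq_len(tile_shape[3])) {
        dname <- .pos_to_name(g$nominal_d + k - 1L, voxel_size[3])
        .write_slice(crop[, , k],
                     file.path(out_path, d1, d2,
                               paste0(d2, "_", dname, ".tif")), 8L)
      }
    }
    gt
  })

  utils::write.csv(gt, file.path(out_path, "ground_truth.csv"),
                   row.names = FALSE)
  list(volume = import_volume(out_path, voxel_size), ground_truth = gt,
       seed = seed)
}

#' True pairwise displacements implied by the ground truth
#'
#' For every adjacent pair the true relative displacement differs from the
#' nominal one by the difference of the two tiles' jitters; this is the
#' quantity pairwise alignment must recover.
#'
#' @param ground_truth Data frame from [tile_phantom()].
#' @return Data frame with one row per adjacent pair: grid indices of both
#'   tiles, adjacency `axis`, and the true offset (relative to nominal) per
#'   direction `true_off_v`, `true_off_h`, `true_off_d`.
#' @export
true_pair_offsets <- function(ground_truth) {
  n_rows <- max(ground_truth$row) + 1L
  n_cols <- max(ground_truth$col) + 1L
  g <- function(r, c) ground_truth[ground_truth$row == r &
                                     ground_truth$col == c, ]
  pairs <- .enumerate_pairs(n_rows, n_cols)
  do.call(rbind, lapply(pairs, function(p) {
    a <- g(p$a_row, p$a_col); b <- g(p$b_row, p$b_col)
    data.frame(a_row = p$a_row, a_col = p$a_col,
               b_row = p$b_row, b_col = p$b_col, axis = p$axis,
               true_off_v = b$jitter_v - a$jitter_v,
               true_off_h = b$jitter_h - a$jitter_h,
               true_off_d = b$jitter_d - a$jitter_d)
  }))
}
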