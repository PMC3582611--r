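# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing is read from stored data.

# Phantom just large enough for the requested grid.
phantom_for <- function(n_rows, n_cols, tile, overlap, jitter_max,
                        density = 1.5, seed = 42, empty_fraction = 0) {
  shape <- c((n_rows - 1) * (tile[1] - overlap[1]) + tile[1] + 2 * jitter_max,
             (n_cols - 1) * (tile[2] - overlap[2]) + tile[2] + 2 * jitter_max,
             tile[3] + 2 * jitter_max)
  make_phantom(shape, content_density = density,
               empty_fraction = empty_fraction, seed = seed)
}

# A generated on-disk tiled volume plus its ground truth and phantom.
make_test_volume <- function(n_rows = 2, n_cols = 2, tile = c(40, 40, 12),
                             overlap = c(12, 12), jitter_max = 2,
                             noise_sigma = 3, seed = 1, density = 1.5,
                             dir = tempfile("vol")) {
  ph <- phantom_for(n_rows, n_cols, tile, overlap, jitter_max,
                    density = density, seed = seed + 1000)
  res <- tile_phantom(ph, n_rows, n_cols, tile, overlap,
                      jitter_max = jitter_max, noise_sigma = noise_sigma,
                      seed = seed, out_path = dir)
  res$phantom <- ph
  res$tile <- tile
  res$overlap <- overlap
  res$jitter_max <- jitter_max
  res
}

# Fabricated in-memory state (no files) for unit tests of selection and
# placement: per-pair offsets/reliabilities set directly.
fake_volume <- function(n_rows, n_cols, tile = c(64L, 64L, 8L),
                        nominal_v = NULL, nominal_h = NULL,
                        nominal_d = NULL) {
  step_v <- tile[1] - 16L
  step_h <- tile[2] - 16L
  tiles <- list()
  for (r in seq_len(n_rows) - 1L) for (c in seq_len(n_cols) - 1L) {
    tiles[[r * n_cols + c + 1L]] <- list(
      row = r, col = c,
      nominal_v = if (is.null(nominal_v)) r * step_v else nominal_v[r * n_cols + c + 1L],
      nominal_h = if (is.null(nominal_h)) c * step_h else nominal_h[r * n_cols + c + 1L],
      nominal_d = if (is.null(nominal_d)) 0L else nominal_d[r * n_cols + c + 1L],
      slice_paths = sprintf("%06d/%06d_%06d/s%03d.tif", r, r, c,
                            seq_len(tile[3])),
      stitchable = TRUE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 tile_height_v = tile[1], tile_width_h = tile[2],
                 n_slices_total = tile[3], voxel_size = c(1, 1, 1),
                 bits = 8L, root_path = "<fake>", tiles = tiles),
            class = "tiled_volume")
}

# Thresholded-stage state over a fake volume; `rel` and `off` are functions
# (pair_index) -> named length-3 vectors, or NULL for defaults.
fake_state <- function(n_rows, n_cols, rel = NULL, off = NULL, ...) {
  vol <- fake_volume(n_rows, n_cols, ...)
  st <- stitch3d:::.new_state("thresholded", vol)
  for (i in seq_along(st$pairs)) {
    r <- if (is.null(rel)) c(V = 0.9, H = 0.9, D = 0.9) else
      stats::setNames(as.numeric(rel(i)), c("V", "H", "D"))
    o <- if (is.null(off)) c(V = 0, H = 0, D = 0) else
      stats::setNames(as.numeric(off(i)), c("V", "H", "D"))
    st$pairs[[i]]$offset <- o
    st$pairs[[i]]$reliability <- r
    st$pairs[[i]]$stitchable <- min(r) > 0
    st$pairs[[i]]$default_flag <- !(min(r) > 0)
  }
  st
}

# Brute-force NCC oracle: scalar quadruple loop, independent of ncc_map.
ncc_oracle <- function(a, b, ds) {
  m <- nrow(a); n <- ncol(a)
  out <- matrix(0, 2 * ds + 1, 2 * ds + 1)
  for (u in -ds:ds) for (v in -ds:ds) {
    sa <- 0; sb <- 0; k <- 0
    for (i in 1:m) for (j in 1:n) {
      if (i + u >= 1 && i + u <= m && j + v >= 1 && j + v <= n) {
        sa <- sa + a[i, j]; sb <- sb + b[i + u, j + v]; k <- k + 1
      }
    }
    ma <- sa / k; mb <- sb / k
    num <- 0; da <- 0; db <- 0
    for (i in 1:m) for (j in 1:n) {
      if (i + u >= 1 && i + u <= m && j + v >= 1 && j + v <= n) {
        x <- a[i, j] - ma; y <- b[i + u, j + v] - mb
        num <- num + x * y; da <- da + x * x; db <- db + y * y
      }
    }
    den <- sqrt(da * db)
    out[u + ds + 1, v + ds + 1] <- if (den == 0) 0 else num / den
  }
  out
}

# Enumerate all spanning trees of a small edge list by brute force and
# return the minimum total weight. Edges: data.frame with node ids a, b
# (1-based) and weight.
min_spanning_weight_exhaustive <- function(edges, n_nodes) {
  m <- nrow(edges)
  best <- Inf
  for (sel in utils::combn(m, n_nodes - 1, simplify = FALSE)) {
    # connectivity check by repeated merging
    comp <- seq_len(n_nodes)
    for (i in sel) {
      ca <- comp[edges$a[i]]; cb <- comp[edges$b[i]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    if (length(unique(comp)) == 1)
      best <- min(best, sum(edges$weight[sel]))
  }
  best
}

# Crop of the phantom that a tile occupies, in phantom coordinates.
phantom_crop <- function(phantom, gt_row, tile) {
  phantom[gt_row$true_v + seq_len(tile[1]),
          gt_row$true_h + seq_len(tile[2]),
          gt_row$true_d + seq_len(tile[3]), drop = FALSE]
}
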