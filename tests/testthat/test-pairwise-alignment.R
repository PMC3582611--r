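test_that("mip matches an exhaustive loop oracle and handles point sources", {
  set.seed(31)
  arr <- array(runif(5 * 6 * 4), dim = c(5, 6, 4))
  expect_equal(mip(arr, "D"), apply(arr, c(1, 2), max))
  expect_equal(mip(arr, "V"), apply(arr, c(2, 3), max))
  expect_equal(mip(arr, "H"), apply(arr, c(1, 3), max))

  z <- array(0, dim = c(4, 4, 3))
  expect_true(all(mip(z, "D") == 0))
  z[2, 3, 2] <- 255
  m <- mip(z, "D")
  expect_equal(sum(m == 255), 1)
  expect_equal(m[2, 3], 255)
})

test_that("ncc_map finds exact self- and translated correlations", {
  set.seed(32)
  img <- matrix(0, 20, 20)
  img[6:14, 6:14] <- matrix(runif(81), 9, 9)

  self <- ncc_map(img, img, 2)
  pk <- peak_and_width(self)
  expect_equal(pk$peak_shift, c(0L, 0L))
  expect_equal(pk$peak_value, 1.0, tolerance = 1e-12)

  # translate content by (1, -2): zero-padded shift, content clear of borders
  tr <- matrix(0, 20, 20)
  tr[7:15, 4:12] <- img[6:14, 6:14]
  m <- ncc_map(img, tr, 4)
  pk <- peak_and_width(m)
  expect_equal(pk$peak_shift, c(1L, -2L))
  expect_equal(pk$peak_value, 1.0, tolerance = 1e-12)

  # constant images: flagged degenerate, all-zero map, no exception
  flat <- matrix(5, 12, 12)
  dm <- ncc_map(flat, flat, 2)
  expect_true(dm$degenerate)
  expect_true(all(dm$values == 0))

  expect_error(ncc_map(matrix(0, 4, 4), matrix(0, 4, 4), 2),
               "strictly larger")
})

test_that("ncc_map equals the brute-force quadruple-loop oracle", {
  set.seed(33)
  for (trial in 1:3) {
    a <- matrix(runif(16 * 16), 16, 16)
    b <- matrix(runif(16 * 16), 16, 16)
    expect_lt(max(abs(ncc_map(a, b, 3)$values - ncc_oracle(a, b, 3))),
              1e-10)
  }
})

test_that("peak location, tie-breaking and widths behave as specified", {
  mk <- function(vals, ds) structure(list(values = vals, delta_search = ds,
                                          degenerate = FALSE),
                                     class = "ncc_map")
  # delta peak at center
  v <- matrix(0, 5, 5); v[3, 3] <- 1
  pk <- peak_and_width(mk(v, 2L))
  expect_equal(pk$peak_shift, c(0L, 0L))
  expect_equal(pk$widths, c(1L, 1L))

  # all-equal positive map: tie-break to zero shift, widths = full side
  pk <- peak_and_width(mk(matrix(0.5, 5, 5), 2L))
  expect_equal(pk$peak_shift, c(0L, 0L))
  expect_equal(pk$widths, c(5L, 5L))

  # discretized Gaussian bump: widths equal a direct threshold-crossing scan
  ds <- 6L
  sh <- seq(-ds, ds)
  g <- exp(-outer(sh^2 / (2 * 2.5^2), sh^2 / (2 * 1.2^2), `+`))
  pk <- peak_and_width(mk(g, ds), width_fraction = 0.75)
  scan_width <- function(line, thr) {
    at <- which.max(line)
    lo <- at; while (lo > 1 && line[lo - 1] >= thr) lo <- lo - 1
    hi <- at; while (hi < length(line) && line[hi + 1] >= thr) hi <- hi + 1
    hi - lo + 1L
  }
  thr <- 0.75 * max(g)
  expect_equal(pk$widths[1], scan_width(g[, ds + 1], thr))
  expect_equal(pk$widths[2], scan_width(g[ds + 1, ], thr))
})

test_that("reliability is bounded and monotone in peak and width", {
  expect_equal(reliability(1.0, 1, 9), 1.0)
  expect_equal(reliability(-0.2, 3, 9), 0.0)
  expect_equal(reliability(0, 1, 9), 0.0)
  expect_equal(reliability(0.8, 1, 9), 0.8)
  for (pv in c(0.2, 0.5, 0.9)) {
    r <- vapply(1:9, function(w) reliability(pv, w, 9), numeric(1))
    expect_true(all(diff(r) <= 0))
    expect_true(all(r >= 0 & r <= 1))
  }
  for (w in c(1, 3, 7)) {
    r <- vapply(seq(0, 1, 0.1), function(p) reliability(p, w, 9), numeric(1))
    expect_true(all(diff(r) >= -1e-12))
  }
})

test_that("overlap ROIs follow nominal geometry", {
  vol <- fake_volume(1, 2, tile = c(64L, 512L, 8L),
                     nominal_h = c(0L, 412L), nominal_v = c(0L, 0L))
  pair <- list(a_row = 0, a_col = 0, b_row = 0, b_col = 1, axis = "H")
  rois <- compute_overlap_rois(vol, pair, delta_search = 0)
  expect_equal(rois$roi_a$h, c(412, 512))  # width 100 = 512 - 412
  expect_equal(rois$roi_b$h, c(0, 100))
  expect_equal(rois$roi_a$v, c(0, 64))
  expect_equal(diff(rois$roi_a$h), diff(rois$roi_b$h))

  # coincident tiles: overlap is the full footprint
  vol2 <- fake_volume(1, 2, tile = c(64L, 512L, 8L),
                      nominal_h = c(0L, 0L), nominal_v = c(0L, 0L))
  rois <- compute_overlap_rois(vol2, pair, delta_search = 0)
  expect_equal(rois$roi_a$h, c(0, 512))

  # disjoint tiles: explicit no-overlap error
  vol3 <- fake_volume(1, 2, tile = c(64L, 512L, 8L),
                      nominal_h = c(0L, 512L), nominal_v = c(0L, 0L))
  expect_error(compute_overlap_rois(vol3, pair), "no overlap")
})

test_that("substack-pair alignment yields 6 candidates, 2 per direction", {
  res <- make_test_volume(1, 2, tile = c(32, 32, 10), overlap = c(12, 12),
                          jitter_max = 0, noise_sigma = 0, seed = 35,
                          density = 15)
  vol <- res$volume
  pair <- list(a_row = 0, a_col = 0, b_row = 0, b_col = 1, axis = "H")
  rois <- compute_overlap_rois(vol, pair, delta_search = 3)
  a <- load_substack(vol, substack_ref(vol, 0, 0, 0, 10))
  b <- load_substack(vol, substack_ref(vol, 0, 1, 0, 10))
  sub_a <- a[(rois$roi_a$v[1] + 1):rois$roi_a$v[2],
             (rois$roi_a$h[1] + 1):rois$roi_a$h[2], , drop = FALSE]
  sub_b <- b[(rois$roi_b$v[1] + 1):rois$roi_b$v[2],
             (rois$roi_b$h[1] + 1):rois$roi_b$h[2], , drop = FALSE]
  out <- align_substack_pair(sub_a, sub_b, align_config(10, 3))
  expect_length(out$candidates, 6)
  dirs <- vapply(out$candidates, `[[`, character(1), "direction")
  expect_equal(as.vector(table(factor(dirs, c("V", "H", "D")))), c(2, 2, 2))

  # perfect data: zero offsets with high confidence
  expect_equal(unname(out$offset), c(0, 0, 0))
  expect_true(all(out$reliability > 0.9))

  # pure independent noise: nothing reliable
  set.seed(36)
  na_ <- array(sample(0:255, 12 * 32 * 10, TRUE), dim = c(12, 32, 10))
  nb <- array(sample(0:255, 12 * 32 * 10, TRUE), dim = c(12, 32, 10))
  noise_out <- align_substack_pair(na_, nb, align_config(10, 3))
  expect_true(all(noise_out$reliability < 0.5))

  # fully constant overlap: degenerate, reliability 0, offset 0, no error
  cz <- array(7, dim = c(12, 32, 10))
  deg <- align_substack_pair(cz, cz, align_config(10, 3))
  expect_equal(unname(deg$reliability), c(0, 0, 0))
  expect_equal(unname(deg$offset), c(0, 0, 0))
})

test_that("align_volume produces one record per pair and layer", {
  res <- make_test_volume(2, 2, tile = c(24, 24, 9), overlap = c(10, 10),
                          jitter_max = 1, noise_sigma = 2, seed = 37)
  st <- align_volume(res$volume, align_config(n_slices = 3, delta_search = 3))
  expect_equal(st$stage, "displacements_computed")
  expect_length(st$pairs, 4)
  for (p in st$pairs) {
    expect_length(p$layers, 3)
    expect_equal(vapply(p$layers, `[[`, integer(1), "z0"), c(0L, 3L, 6L))
  }

  # preview: restricting to one layer yields records only for that layer
  stp <- align_volume(res$volume, align_config(n_slices = 3, delta_search = 3),
                      slice_range = c(3, 6))
  for (p in stp$pairs) {
    expect_length(p$layers, 1)
    expect_equal(p$layers[[1]]$z0, 3L)
  }
  expect_error(align_volume(res$volume, align_config(3, 3),
                            row_range = c(1, 1)),
               "empty subvolume")
})

test_that("alignment honors the streaming memory and read-once contracts", {
  res <- make_test_volume(3, 4, tile = c(20, 20, 4), overlap = c(8, 8),
                          jitter_max = 1, noise_sigma = 2, seed = 38)
  reset_io_stats()
  align_volume(res$volume, align_config(n_slices = 4, delta_search = 2))
  st <- io_stats()
  # min(3, 4) + 1 substacks resident at peak
  expect_equal(st$peak_resident_substacks, 4L)
  # every slice read exactly once: 12 tiles x 4 slices, no repeats
  expect_equal(st$slice_reads, 48L)
  expect_equal(st$distinct_slice_reads, 48L)

  res2 <- make_test_volume(2, 2, tile = c(20, 20, 6), overlap = c(8, 8),
                           jitter_max = 1, noise_sigma = 2, seed = 39)
  reset_io_stats()
  align_volume(res2$volume, align_config(n_slices = 3, delta_search = 2))
  expect_equal(io_stats()$peak_resident_substacks, 3L)
})
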