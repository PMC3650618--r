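test_that("gradient tables partition shells and validate input", {
  gt <- hardi_scheme()
  expect_identical(as.integer(table(gt$shell)), c(2L, 6L, 64L))
  expect_lt(max(abs(sqrt(rowSums(gt$bvecs[gt$shell != "b0", ]^2)) - 1)),
            1e-12)
  expect_error(gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero gradient")
  expect_error(gradient_table(c(0, 1000), matrix(1, 3, 3)), "match")
  expect_error(gradient_table(1000, rbind(c(1, 0, 0))), "normalisation")
})

test_that("gradient tables round-trip through FSL-dialect text files", {
  gt <- hardi_scheme()
  d <- withr::local_tempdir()
  write_gradients(gt, file.path(d, "x.bval"), file.path(d, "x.bvec"))
  gt2 <- read_gradients(file.path(d, "x.bval"), file.path(d, "x.bvec"))
  expect_equal(gt2$bvals, gt$bvals)
  expect_lt(max(abs(gt2$bvecs - gt$bvecs)), 1e-12)
  expect_error(read_gradients(file.path(d, "nope.bval"),
                              file.path(d, "x.bvec")), "not found")
})

test_that("DWI volumes and masks round-trip through NIfTI bit-identically", {
  sim <- phantom_pipeline("STRAIGHT")$sim
  d <- withr::local_tempdir()
  paths <- write_phantom(sim, d, "ph")
  rd <- read_dwi(paths[["dwi"]], paths[["bval"]], paths[["bvec"]])
  expect_identical(dim(rd$volume$data), dim(sim$volume$data))
  expect_identical(max(abs(rd$volume$data - sim$volume$data)), 0)
  expect_identical(max(abs(rd$volume$affine - sim$volume$affine)), 0)
  m <- read_mask(paths[["brain"]])
  expect_identical(m$data, sim$brain$data)
})

test_that("reading rejects mismatched image / gradient table pairs", {
  d <- withr::local_tempdir()
  vol <- dwi_volume(array(1, c(3, 3, 3, 4)))
  write_dwi(vol, file.path(d, "v.nii.gz"))
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  write_gradients(gt, file.path(d, "v.bval"), file.path(d, "v.bvec"))
  expect_error(read_dwi(file.path(d, "v.nii.gz"), file.path(d, "v.bval"),
                        file.path(d, "v.bvec")), "4 volumes")
})

test_that("isotropic resampling preserves constants, grids and linear fields", {
  const <- dwi_volume(array(5, c(4, 4, 4, 2)), diag(c(2, 2, 2, 1)))
  rs <- resample_isotropic(const, 1)
  expect_identical(dim(rs$data)[1:3], c(8L, 8L, 8L))
  expect_equal(rs$voxel_size, c(1, 1, 1))
  expect_equal(max(abs(rs$data - 5)), 0)
  # trilinear interpolation reproduces an affine intensity field exactly
  ramp <- array(rep(seq_len(10), times = 6 * 6), c(10, 6, 6, 1))
  rr <- resample_isotropic(dwi_volume(ramp, diag(c(2, 2, 2, 1))), 1)
  xw <- (rr$affine %*% rbind(seq_len(dim(rr$data)[1]) - 1, 2, 2, 1))[1, ]
  interior <- xw >= 0 & xw <= 18        # inside the original centre range
  expect_lt(max(abs(rr$data[interior, 3, 3, 1] - (1 + xw[interior] / 2))),
            1e-12)
  expect_error(resample_isotropic(const, -1), "positive")
  expect_error(resample_isotropic(const, 9), "4x")
})

test_that("tractograms round-trip through .trk and .tck within 1e-3 mm", {
  px <- phantom_pipeline("STRAIGHT")
  tg <- track_whole_brain(px$peaks, px$sim$brain,
                          tracking_config(seeds_per_voxel = 8))
  d <- withr::local_tempdir()
  for (ext in c("trk", "tck")) {
    f <- file.path(d, paste0("t.", ext))
    write_tractogram(tg, f)
    back <- read_tractogram(f)
    expect_identical(length(back$streamlines), length(tg$streamlines))
    dev <- max(mapply(function(a, b) max(abs(a$points - b$points)),
                      tg$streamlines, back$streamlines))
    expect_lt(dev, 1e-3)
  }
  # single tiny streamline and the empty tractogram are valid files
  one <- tractogram(list(streamline(rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(2, 0, 0)))),
                    diag(4), c(5L, 5L, 5L))
  f1 <- file.path(d, "one.trk")
  write_tractogram(one, f1)
  r1 <- read_tractogram(f1)
  expect_identical(length(r1$streamlines), 1L)
  expect_identical(nrow(r1$streamlines[[1]]$points), 3L)
  empty <- tractogram(list(), diag(4), c(5L, 5L, 5L))
  f0 <- file.path(d, "none.tck")
  write_tractogram(empty, f0)
  expect_identical(length(read_tractogram(f0)$streamlines), 0L)
  expect_error(write_tractogram(one, file.path(d, "t.xyz")), "extension")
})

test_that("world/voxel conversion is consistent with the affine", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(10, -4, 0)
  idx <- rbind(c(0, 0, 0), c(3, 2, 1))
  w <- voxel_to_world(idx, aff)
  expect_equal(w, rbind(c(10, -4, 0), c(16, 0, 2)))
  expect_identical(world_to_voxel(w, aff), matrix(as.integer(idx), 2, 3))
  # points just off-centre resolve to the nearest voxel
  expect_identical(drop(world_to_voxel(c(10.9, -4, 0), aff)), c(0L, 0L, 0L))
  expect_identical(drop(world_to_voxel(c(11.1, -4, 0), aff)), c(1L, 0L, 0L))
})
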