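test_that("resample_z follows the slice-count formula and interpolates linearly", {
  set.seed(42)
  vol <- array(rnorm(6 * 5 * 8), dim = c(6, 5, 8))
  s <- ct_series(vol, slice_spacing_mm = 2)

  out <- resample_z(s, 1)
  expect_equal(dim(out$slices)[3], floor((8 - 1) * 2 / 1) + 1)  # 15
  expect_equal(out$slice_spacing_mm, 1)

  # coordinate-by-coordinate oracle: every voxel column interpolated with
  # approx() at the output positions
  src_z <- (0:7) * 2
  out_z <- (0:14) * 1
  for (r in c(1, 4)) for (cc in c(2, 5)) {
    ref <- approx(src_z, vol[r, cc, ], xout = out_z)$y
    expect_equal(out$slices[r, cc, ], ref, tolerance = 1e-12)
  }
  # first slice preserved exactly
  expect_identical(out$slices[, , 1], vol[, , 1])
})

test_that("resample_z identity and midpoint cases are exact", {
  vol <- array(runif(4 * 4 * 5), dim = c(4, 4, 5))
  s <- ct_series(vol, slice_spacing_mm = 1.5)
  expect_identical(resample_z(s, 1.5)$slices, vol)

  two <- ct_series(array(rep(c(0, 10), each = 9), dim = c(3, 3, 2)), 2)
  mid <- resample_z(two, 1)
  expect_equal(dim(mid$slices)[3], 3)
  expect_equal(unique(as.vector(mid$slices[, , 2])), 5)
})

test_that("resample_z down-up round trip restores original slice values", {
  set.seed(7)
  vol <- array(rnorm(5 * 5 * 9), dim = c(5, 5, 9))
  s <- ct_series(vol, slice_spacing_mm = 2)
  back <- resample_z(resample_z(s, 1), 2)
  expect_equal(dim(back$slices)[3], 9)
  expect_equal(back$slices, vol, tolerance = 1e-6)
})

test_that("resample_z rejects degenerate inputs", {
  one <- ct_series(array(0, dim = c(3, 3, 1)), 1)
  expect_error(resample_z(one, 0.5), "single-slice")
  s <- ct_series(array(0, dim = c(3, 3, 4)), 1)
  expect_error(resample_z(s, 0), "positive")
  expect_error(ct_series(array(0, dim = c(3, 3, 4)), -1), "positive")
})

test_that("extract_slab picks the [k-5, k+4] slice window", {
  s <- slice_index_series(64)
  ann <- nodule_annotation(20, c(25, 25), c(35, 35), 1, n_slices = 64)
  patch <- extract_slab(s, ann, "small30", window = c(0, 63))
  expect_equal(dim(patch), c(30, 30, 10))
  # slice z of the patch holds normalized value (15 + z - 1)/63
  got <- apply(unclass(patch), 3, function(m) unique(as.vector(m)))
  expect_equal(got, (15:24) / 63, tolerance = 1e-12)

  large <- extract_slab(s, ann, "large40", window = c(0, 63))
  expect_equal(dim(large), c(40, 40, 10))
})

test_that("extract_slab replicates edges for boundary annotations", {
  s <- slice_index_series(12)
  ann <- nodule_annotation(0, c(1, 1), c(4, 4), 0, n_slices = 12)
  patch <- extract_slab(s, ann, "small30", window = c(0, 11))
  expect_equal(dim(patch), c(30, 30, 10))
  # slices below index 0 are copies of slice 0
  expect_true(all(patch[, , 1:6] == 0))
  expect_equal(unique(as.vector(patch[, , 7])), 1 / 11)
})

test_that("the bbox center lands at the patch's central in-plane position", {
  vol <- array(0, dim = c(80, 80, 30))
  vol[41, 53, 16] <- 1  # 0-based (40, 52, 15)
  s <- ct_series(vol, 1)
  # half-open boxes [36,45) x [48,57): integer center (40, 52) 0-based
  ann <- nodule_annotation(15, c(36, 48), c(45, 57), 1, n_slices = 30)
  patch <- extract_slab(s, ann, "small30", window = c(0, 1))
  hot <- which(unclass(patch) == 1, arr.ind = TRUE)
  expect_equal(nrow(hot), 1L)
  # central in-plane index for a 30-wide patch is 16 (1-based); slice
  # offset 5 (0-based) is the 6th slab slice
  expect_equal(unname(hot[1, ]), c(16, 16, 6))
})

test_that("normalize_intensity maps the window affinely onto [0,1]", {
  expect_equal(normalize_intensity(c(-1000, 400), c(-1000, 400)), c(0, 1))
  expect_equal(normalize_intensity(-300, c(-1000, 400)), 0.5)
  expect_equal(normalize_intensity(array(450, c(2, 2, 2)), c(-1000, 400)),
               array(1, c(2, 2, 2)))
  expect_error(normalize_intensity(1, c(5, 5)), "low < high")
})

test_that("build_visit_sequence sorts, computes day lapses and is order-invariant", {
  make_rows <- function(dates) {
    data.frame(patient_id = "P1", visit_date = dates, center_slice = 8L,
               bbox_r0 = 20L, bbox_c0 = 20L, bbox_r1 = 28L, bbox_c1 = 28L,
               label = 1L)
  }
  dates <- c("2015-01-01", "2015-04-03", "2015-07-03")  # gaps 92, 91
  series <- lapply(dates, function(d) {
    ct_series(array(runif(48 * 48 * 16), c(48, 48, 16)), 1, visit_date = d)
  })
  seqs <- build_visit_sequence(make_rows(dates), series, window = c(0, 1))
  expect_length(seqs, 3)
  expect_equal(vapply(seqs, `[[`, numeric(1), "delta_days"), c(0, 92, 91))
  expect_equal(dim(seqs[[1]]$small30), c(30, 30, 10))
  expect_equal(dim(seqs[[1]]$large40), c(40, 40, 10))

  shuf <- c(3, 1, 2)
  seqs2 <- build_visit_sequence(make_rows(dates)[shuf, ], series[shuf],
                                window = c(0, 1))
  expect_equal(seqs2, seqs)

  single <- build_visit_sequence(make_rows(dates[1]), series[1],
                                 window = c(0, 1))
  expect_length(single, 1)
  expect_equal(single[[1]]$delta_days, 0)

  dup <- make_rows(c("2015-01-01", "2015-01-01"))
  expect_error(build_visit_sequence(dup, series[1:2], window = c(0, 1)),
               "duplicate")
})

test_that("nifti round trip preserves voxels and spacing", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  vol <- array(runif(20 * 20 * 8), c(20, 20, 8))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(0.7, 0.7, 2.5)
  path <- file.path(dir, "v.nii.gz")
  RNifti::writeNifti(img, path)
  s <- read_nifti_series(path, patient_id = "P9")
  expect_equal(s$slice_spacing_mm, 2.5, tolerance = 1e-6)
  expect_equal(dim(s$slices), c(20, 20, 8))
  expect_equal(s$slices, vol, tolerance = 1e-6)
})
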