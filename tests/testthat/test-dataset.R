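test_that("HU window is inclusive at both bounds (brute-force 3x3 enumeration)", {
  hu <- matrix(c(-31, -30, -29, -28, 0, 149, 150, 151, 152), 3, 3)
  roi <- matrix(1L, 3, 3)
  gt <- apply_hu_filter(hu, roi)
  # independent oracle: explicit pixel-by-pixel window test
  expected <- matrix(0L, 3, 3)
  for (i in seq_len(9)) expected[i] <- as.integer(roi[i] == 1L && hu[i] >= -29 && hu[i] <= 150)
  expect_identical(unclass(gt)[, ], expected[, ])
  expect_equal(sum(gt), 5)            # -29, -28, 0, 149, 150 survive
  expect_equal(gt[3, 1], 1L)          # exactly -29 retained
  expect_equal(gt[2, 1], 0L)          # -30 removed
  expect_equal(gt[1, 3], 1L)          # exactly +150 retained
  expect_equal(gt[2, 3], 0L)          # +151 removed
})

test_that("empty ROI gives an empty ground truth; custom windows honoured", {
  hu <- matrix(50, 4, 4)
  expect_true(all(apply_hu_filter(hu, matrix(0L, 4, 4)) == 0L))
  expect_true(all(apply_hu_filter(hu, matrix(1L, 4, 4), 0, 40) == 0L))
  expect_error(apply_hu_filter(hu, matrix(1L, 4, 4), 10, -10), "hu_lo")
  expect_error(apply_hu_filter(hu, matrix(1L, 3, 3)), "shape")
})

test_that("noiseless phantom ground truth equals the ROI exactly", {
  ph <- generate_phantom(noiseless_spec(), seed = 2)
  gt <- apply_hu_filter(ph$image, ph$mask)
  expect_equal(sum(gt != ph$mask), 0)
})

test_that("ground truth is a subset of the ROI and filtering is idempotent", {
  set.seed(99)
  for (i in 1:20) {
    hu <- matrix(sample(-200:300, 64, replace = TRUE), 8, 8)
    roi <- random_mask(8, 8)
    gt <- apply_hu_filter(hu, roi)
    expect_true(all(gt <= roi))
    gt2 <- apply_hu_filter(hu, gt)
    expect_equal(unclass(gt2)[, ], unclass(gt)[, ])
  }
})

test_that("a 256-patient 6:2:2 split gives 154/51/51 patients (616/204/204 slices)", {
  sp <- split_by_patient(sprintf("P%04d", 1:256), seed = 1)
  expect_length(sp$train, 154)
  expect_length(sp$val, 51)
  expect_length(sp$test, 51)
  expect_equal(4 * c(length(sp$train), length(sp$val), length(sp$test)),
               c(616, 204, 204))
})

test_that("splits are exhaustive, disjoint and patient-leakage-free for random n", {
  set.seed(4)
  for (n in c(3, 10, sample(3:1000, 10))) {
    ids <- sprintf("P%04d", seq_len(n))
    sp <- split_by_patient(ids, seed = n)
    all_assigned <- c(sp$train, sp$val, sp$test)
    expect_setequal(all_assigned, ids)
    expect_equal(length(all_assigned), n)  # no id twice => pairwise disjoint
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
  }
  sp10 <- split_by_patient(sprintf("P%02d", 1:10), seed = 3)
  expect_equal(lengths(sp10[c("train", "val", "test")]),
               c(train = 6L, val = 2L, test = 2L))
})

test_that("split is deterministic in the seed and validates its inputs", {
  ids <- sprintf("P%03d", 1:40)
  expect_identical(split_by_patient(ids, seed = 12), split_by_patient(ids, seed = 12))
  expect_false(identical(split_by_patient(ids, seed = 12)$train,
                         split_by_patient(ids, seed = 13)$train))
  expect_error(split_by_patient(ids, ratios = c(0.5, 0.3, 0.3)), "sum")
  expect_error(split_by_patient(ids[1:2]), "at least 3")
  expect_error(split_by_patient(c("A", "A", "B")), "unique")
})

test_that("cohort write/read round-trips HU bit-exactly via TIFF + manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(2, tiny_spec(size = 32), seed = 6)
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_cohort(dir)
  expect_equal(length(back), 2)
  for (p in 1:2) for (k in 1:4) {
    expect_identical(back[[p]]$slices[[k]]$image, coh[[p]]$slices[[k]]$image)
    expect_identical(back[[p]]$slices[[k]]$mask, coh[[p]]$slices[[k]]$mask)
  }
})

test_that("read_slice applies the linear rescale and rejects uncalibrated input", {
  dir <- withr::local_tempdir()
  # stored value 1024 with slope 1, intercept -1024 must read as 0 HU
  tiff::writeTIFF(matrix(1024 / 65535, 8, 8), file.path(dir, "s.tif"),
                  bits.per.sample = 16L)
  img <- read_slice(file.path(dir, "s.tif"), rescale_slope = 1, rescale_intercept = -1024)
  expect_true(all(img == 0L))
  expect_error(read_slice(file.path(dir, "s.tif")), "calibration")
  tiff::writeTIFF(matrix(0.5, 4, 6), file.path(dir, "rect.tif"), bits.per.sample = 16L)
  expect_error(read_slice(file.path(dir, "rect.tif"), 1, 0), "square")
})

test_that("HU normalisation is the fixed clipped linear map", {
  expect_equal(normalize_hu(matrix(-1024, 1, 1))[1, 1], 0)
  expect_equal(normalize_hu(matrix(1024, 1, 1))[1, 1], 1)
  expect_equal(normalize_hu(matrix(0, 1, 1))[1, 1], 0.5)
  expect_equal(normalize_hu(matrix(3000, 1, 1))[1, 1], 1)  # clipped
  expect_equal(normalize_hu(matrix(-2000, 1, 1))[1, 1], 0)
})
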