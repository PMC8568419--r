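test_that("identity parameters return image and mask bit-identically", {
  ph <- generate_phantom(tiny_spec(), seed = 1)
  out <- apply_augment(ph$image, ph$mask, augment_params())
  expect_identical(out$image, ph$image)
  expect_identical(out$mask, ph$mask)
})

test_that("horizontal flip is an exact involution", {
  ph <- generate_phantom(tiny_spec(), seed = 2)
  p <- augment_params(hflip = TRUE)
  once <- apply_augment(ph$image, ph$mask, p)
  expect_false(identical(once$image, ph$image))
  twice <- apply_augment(once$image, once$mask, p)
  expect_identical(twice$image, ph$image)
  expect_identical(twice$mask, ph$mask)
})

test_that("sampled parameters always respect the 5% shift and 20 degree bounds", {
  set.seed(10)
  draws <- replicate(10000, unclass(sample_augment_params()), simplify = FALSE)
  dx <- vapply(draws, `[[`, numeric(1), "dx")
  dy <- vapply(draws, `[[`, numeric(1), "dy")
  ang <- vapply(draws, `[[`, numeric(1), "angle_deg")
  hf <- vapply(draws, `[[`, logical(1), "hflip")
  expect_lte(max(abs(dx)), 0.05)
  expect_lte(max(abs(dy)), 0.05)
  expect_lte(max(abs(ang)), 20)
  # flip frequency inside the central 99% binomial interval
  # (oracle: qbinom bounds for Binomial(10000, 0.5))
  expect_gte(sum(hf), qbinom(0.005, 10000, 0.5))
  expect_lte(sum(hf), qbinom(0.995, 10000, 0.5))
})

test_that("parameter sampling is reproducible from a seed", {
  a <- sample_augment_params(seed = 33)
  b <- sample_augment_params(seed = 33)
  expect_identical(a, b)
  expect_error(augment_params(dx = 0.2), "shift")
  expect_error(augment_params(angle_deg = 45), "angle")
})

test_that("a pure +5% horizontal shift moves the mask centroid 5 px on a 100 px image", {
  mask <- matrix(0L, 100, 100)
  mask[45:55, 40:50] <- 1L   # single blob, fully in frame after the shift
  img <- matrix(0L, 100, 100); img[mask == 1L] <- 60L
  out <- apply_augment(img, mask, augment_params(dx = 0.05))
  centroid <- function(m) c(mean(row(m)[m == 1]), mean(col(m)[m == 1]))
  # oracle: brute-force centroid before/after
  expect_equal(centroid(out$mask) - centroid(mask), c(0, 5), tolerance = 1e-12)
  out_v <- apply_augment(img, mask, augment_params(dy = -0.05))
  expect_equal(centroid(out_v$mask) - centroid(mask), c(-5, 0), tolerance = 1e-12)
})

test_that("augmentation preserves mask binarity and near-conserves in-frame area", {
  ph <- generate_phantom(noiseless_spec(128), seed = 4)
  set.seed(5)
  for (i in 1:20) {
    p <- sample_augment_params()
    out <- apply_augment(ph$image, ph$mask, p)
    expect_true(all(out$mask %in% c(0L, 1L)))
    # compartments sit centrally, so the foreground stays in frame
    expect_lte(abs(sum(out$mask) - sum(ph$mask)) / sum(ph$mask), 0.03)
  }
})

test_that("mask transform agrees with re-deriving the mask from the warped image", {
  # noiseless phantom: warp the image bilinearly, re-derive the ground truth by
  # HU-filtering inside the warped ROI, and compare with the directly warped
  # ground truth
  ph <- generate_phantom(noiseless_spec(128), seed = 6)
  gt <- apply_hu_filter(ph$image, ph$mask)
  set.seed(7)
  js <- replicate(100, {
    p <- sample_augment_params()
    out <- apply_augment(ph$image, gt, p)
    rederived <- apply_hu_filter(out$image, out$mask)
    jaccard(rederived, out$mask)
  })
  expect_gte(min(js), 0.98)
})

test_that("dataset augmentation multiplies counts and keeps originals first", {
  coh <- generate_cohort(2, tiny_spec(size = 32), seed = 3)
  pairs <- cohort_pairs(coh)
  aug <- augment_dataset(pairs, factor = 5, seed = 9)
  expect_length(aug, 5 * length(pairs))
  expect_identical(aug[[1]]$image, pairs[[1]]$image)      # original retained
  expect_identical(augment_dataset(pairs, factor = 1, seed = 9), pairs)
  expect_error(augment_dataset(pairs, factor = 0), "factor")
})

test_that("recorded provenance replays each augmented copy bit-exactly", {
  coh <- generate_cohort(1, tiny_spec(size = 32), seed = 8)
  pairs <- cohort_pairs(coh)
  aug <- augment_dataset(pairs, factor = 3, seed = 21)
  copies <- Filter(function(x) !is.null(x$params), aug)
  expect_length(copies, 8)
  for (cp in copies) {
    replay <- apply_augment(pairs[[cp$source_index]]$image,
                            pairs[[cp$source_index]]$mask, cp$params)
    expect_identical(replay$image, cp$image)
    expect_identical(replay$mask, cp$mask)
  }
})

test_that("augmentation is deterministic in its seed", {
  coh <- generate_cohort(1, tiny_spec(size = 32), seed = 2)
  pairs <- cohort_pairs(coh)
  expect_identical(augment_dataset(pairs, factor = 4, seed = 5),
                   augment_dataset(pairs, factor = 4, seed = 5))
  expect_false(identical(augment_dataset(pairs, factor = 4, seed = 5),
                         augment_dataset(pairs, factor = 4, seed = 6)))
})
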