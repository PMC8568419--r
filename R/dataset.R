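#' Restrict a manual ROI to the skeletal-muscle HU window
#'
#' The ground-truth mask used for training is the manually drawn ROI with
#' every pixel whose attenuation falls outside the skeletal-muscle window
#' removed. Both bounds are inclusive, the standard body-composition
#' convention: a pixel survives iff `roi == 1` and `hu_lo <= HU <= hu_hi`.
#'
#' @param image Integer/numeric HU matrix.
#' @param roi Binary 0/1 ROI matrix of the same shape.
#' @param hu_lo,hu_hi Window bounds in HU; defaults are the skeletal-muscle
#'   window `[-29, 150]`.
#' @return A 0/1 integer matrix, pixel-wise `<= roi`, with attribute
#'   `hu_window = c(hu_lo, hu_hi)`.
#' @examples
#' img <- matrix(c(-30, -29, 150, 151), 2, 2)
#' roi <- matrix(1L, 2, 2)
#' apply_hu_filter(img, roi)   # keeps exactly -29 and 150
#' @export
apply_hu_filter <- function(image, roi, hu_lo = -29, hu_hi = 150) {
  if (hu_lo > hu_hi) stopf("hu_lo (%g) must not exceed hu_hi (%g)", hu_lo, hu_hi)
  check_same_shape(image, roi)
  if (!is_binary_mask(roi)) stopf("roi must be a binary 0/1 matrix")
  gt <- matrix(as.integer(roi == 1L & image >= hu_lo & image <= hu_hi),
               nrow(image), ncol(image))
  attr(gt, "hu_window") <- c(hu_lo, hu_hi)
  gt
}

#' Patient-level train/validation/test split
#'
#' Shuffles patient ids with a seeded RNG and assigns the first
#' `round(r_train * n)` to training, the next `round(r_val * n)` to validation
#' (round-half-up) and the remainder to test, so no patient contributes slices
#' to more than one partition. With 256 patients and the default 6:2:2 ratios
#' this yields 154/51/51 patients.
#'
#' @param ids Character vector of patient ids (>= 3, unique).
#' @param ratios Numeric length-3 vector summing to 1; default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed for the shuffle.
#' @return A `dataset_split`: list with `train`, `val`, `test` id vectors plus
#'   the `ratios` and `seed` used.
#' @examples
#' sp <- split_by_patient(sprintf("P%03d", 1:10), seed = 1)
#' lengths(sp[c("train", "val", "test")])  # 6 2 2
#' @export
split_by_patient <- function(ids, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stopf("ratios must be three numbers summing to 1 (got sum %.12g)", sum(ratios))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stopf("patient ids must be unique")
  n <- length(ids)
  if (n < 3L) stopf("need at least 3 patients to split (got %d)", n)
  n_train <- round_half_up(ratios[1] * n)
  n_val <- round_half_up(ratios[2] * n)
  if (n_train + n_val > n) stopf("ratios leave no patients for the test set")
  perm <- local_seed(seed, sample(ids))
  structure(list(train = perm[seq_len(n_train)],
                 val = perm[n_train + seq_len(n_val)],
                 test = perm[-seq_len(n_train + n_val)],
                 ratios = ratios, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split (seed %s): %d train / %d val / %d test patients\n",
              format(x$seed), length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Map HU to the network input range
#'
#' Fixed, dataset-independent linear map from HU in `[-1024, 1024]` to
#' `[0, 1]`, clipping outside. Keeping the map fixed (rather than per-image
#' min/max) preserves the contrast of the muscle window across slices and
#' makes inference deterministic.
#'
#' @param image HU matrix.
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_hu <- function(image) {
  pmin(pmax((image + 1024) / 2048, 0), 1)
}

#' Write a cohort to disk as 16-bit TIFF slices plus a manifest
#'
#' Slices are stored as 16-bit grayscale TIFF holding `HU + 1024` (the DICOM
#' rescale convention with slope 1, intercept -1024); masks as 8-bit PNG with
#' values 0/1. A TSV manifest records, per slice, the image and mask paths,
#' patient id, slice index and the rescale slope/intercept needed to recover
#' HU. Reading a PNG without this calibration is an error — raw stored values
#' are never silently taken as HU.
#'
#' @param cohort A cohort (list of patient records).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in cohort) {
    for (sl in rec$slices) {
      stem <- sprintf("%s_s%02d", sl$patient_id, sl$slice_index)
      ipath <- file.path("images", paste0(stem, ".tif"))
      mpath <- file.path("masks", paste0(stem, "_mask.png"))
      stored <- sl$image + 1024L
      if (any(stored < 0L) || any(stored > 65535L))
        stopf("HU out of storable range for %s", stem)
      tiff::writeTIFF(stored / 65535, file.path(dir, ipath), bits.per.sample = 16L)
      png::writePNG(sl$mask / 255, file.path(dir, mpath))
      rows[[length(rows) + 1L]] <- data.frame(
        image = ipath, mask = mpath, patient_id = sl$patient_id,
        slice_index = sl$slice_index, rescale_slope = 1,
        rescale_intercept = -1024, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_manifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.tsv") else dir
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read one CT slice as Hounsfield units
#'
#' Reads a 16-bit grayscale TIFF and applies the linear rescale
#' `HU = stored * slope + intercept`. The calibration comes either from
#' explicit arguments or from the slice's manifest row; without it the
#' function refuses to guess.
#'
#' @param path TIFF path.
#' @param rescale_slope,rescale_intercept Linear HU calibration.
#' @param manifest Optional manifest data frame (from [read_manifest()]) whose
#'   row matching `basename(path)` supplies the calibration.
#' @return Integer HU matrix.
#' @export
read_slice <- function(path, rescale_slope = NULL, rescale_intercept = NULL,
                       manifest = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (is.null(rescale_slope) || is.null(rescale_intercept)) {
    if (is.null(manifest))
      stopf("no HU calibration for %s: supply rescale_slope/rescale_intercept or a manifest", path)
    hit <- manifest[basename(manifest$image) == basename(path), , drop = FALSE]
    if (nrow(hit) != 1L)
      stopf("no HU calibration for %s: not found in manifest", path)
    rescale_slope <- hit$rescale_slope
    rescale_intercept <- hit$rescale_intercept
  }
  v <- tiff::readTIFF(path)
  if (length(dim(v)) != 2L) stopf("expected a single-channel image: %s", path)
  if (nrow(v) != ncol(v)) stopf("expected a square slice, got %dx%d: %s",
                                nrow(v), ncol(v), path)
  stored <- round(v * 65535)
  matrix(as.integer(stored * rescale_slope + rescale_intercept), nrow(v), ncol(v))
}

#' @rdname read_slice
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) != 2L) stopf("expected a single-channel mask: %s", path)
  m <- matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
  if (!is_binary_mask(m)) stopf("mask is not binary 0/1: %s", path)
  m
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv`.
#' @return A cohort list in the same structure [generate_cohort()] produces.
#' @export
read_cohort <- function(dir) {
  man <- read_manifest(dir)
  lapply(split(man, man$patient_id)[unique(man$patient_id)], function(pm) {
    pm <- pm[order(pm$slice_index), , drop = FALSE]
    slices <- lapply(seq_len(nrow(pm)), function(i) {
      list(image = read_slice(file.path(dir, pm$image[i]),
                              pm$rescale_slope[i], pm$rescale_intercept[i]),
           mask = read_mask(file.path(dir, pm$mask[i])),
           patient_id = pm$patient_id[i], slice_index = pm$slice_index[i])
    })
    list(patient_id = pm$patient_id[1], slices = slices)
  })
}

#' Write a split assignment as TSV
#' @param split A `dataset_split`.
#' @param path Output TSV path.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    patient_id = c(split$train, split$val, split$test),
    partition = rep(c("train", "val", "test"),
                    c(length(split$train), length(split$val), length(split$test))),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
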