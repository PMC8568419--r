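#' Specification of a synthetic abdominal CT phantom
#'
#' Parameterises an axial abdominal cross-section used to exercise the whole
#' segmentation pipeline without clinical data: an elliptical body on an air
#' background, a vertebral body of bone, and six paravertebral muscle
#' compartments (left/right psoas, quadratus lumborum, paraspinal) embedded in
#' fat-equivalent soft tissue. Compartment HU are drawn from Gaussian tissue
#' distributions; muscle defaults sit well inside the skeletal-muscle window
#' of [-29, 150] HU so the HU-filtered ground truth retains almost all ROI
#' pixels.
#'
#' @param image_size Pixels per side (square slice); must be even and >= 32.
#' @param body_axes Semi-axes of the body ellipse in pixels, `c(row, col)`;
#'   default `c(0.30, 0.40) * image_size`.
#' @param muscle_hu_mean,muscle_hu_sd Muscle HU distribution; the mean must lie
#'   inside `[-29, 150]`.
#' @param fat_hu_mean,fat_hu_sd Fat/soft-tissue HU distribution; mean below -29.
#' @param bone_hu_mean,bone_hu_sd Vertebral bone HU distribution; mean above 150.
#' @param air_hu Constant HU outside the body; at most -900.
#' @param noise_sd Additive Gaussian acquisition noise in HU, applied to the
#'   whole slice before integer quantisation.
#' @param per_patient_jitter Half-width of the uniform fractional jitter applied
#'   to compartment centres and axes, drawn once per patient.
#' @param muscle_scale Multiplier on the muscle compartment semi-axes; 0 gives
#'   an empty ROI.
#' @param hu_lo,hu_hi The muscle HU window the downstream ground-truth filter
#'   will use (carried for reference; not applied here).
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(image_size = 512L,
                         body_axes = NULL,
                         muscle_hu_mean = 60, muscle_hu_sd = 20,
                         fat_hu_mean = -100, fat_hu_sd = 20,
                         bone_hu_mean = 700, bone_hu_sd = 150,
                         air_hu = -1000,
                         noise_sd = 10,
                         per_patient_jitter = 0.10,
                         muscle_scale = 1,
                         hu_lo = -29, hu_hi = 150) {
  image_size <- as.integer(image_size)
  if (is.null(body_axes)) body_axes <- c(0.30, 0.40) * image_size
  spec <- structure(
    list(image_size = image_size, body_axes = body_axes,
         muscle_hu_mean = muscle_hu_mean, muscle_hu_sd = muscle_hu_sd,
         fat_hu_mean = fat_hu_mean, fat_hu_sd = fat_hu_sd,
         bone_hu_mean = bone_hu_mean, bone_hu_sd = bone_hu_sd,
         air_hu = air_hu, noise_sd = noise_sd,
         per_patient_jitter = per_patient_jitter,
         muscle_scale = muscle_scale,
         hu_lo = hu_lo, hu_hi = hu_hi),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param spec A `phantom_spec`.
#' @export
validate_phantom_spec <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("not a phantom_spec object")
  s <- spec
  if (s$image_size < 32L || s$image_size %% 2L != 0L)
    stopf("phantom_spec: image_size must be even and >= 32 (got %d)", s$image_size)
  if (s$muscle_hu_mean < -29 || s$muscle_hu_mean > 150)
    stopf("phantom_spec: muscle_hu_mean must lie in [-29, 150] (got %g)", s$muscle_hu_mean)
  if (s$fat_hu_mean >= -29)
    stopf("phantom_spec: fat_hu_mean must be below -29 HU (got %g)", s$fat_hu_mean)
  if (s$bone_hu_mean <= 150)
    stopf("phantom_spec: bone_hu_mean must be above +150 HU (got %g)", s$bone_hu_mean)
  if (s$air_hu > -900)
    stopf("phantom_spec: air_hu must be at most -900 HU (got %g)", s$air_hu)
  if (length(s$body_axes) != 2L || any(s$body_axes <= 0))
    stopf("phantom_spec: body_axes must be two positive semi-axes")
  for (f in c("muscle_hu_sd", "fat_hu_sd", "bone_hu_sd", "noise_sd"))
    if (s[[f]] < 0) stopf("phantom_spec: %s must be non-negative", f)
  if (s$per_patient_jitter < 0 || s$per_patient_jitter > 0.5)
    stopf("phantom_spec: per_patient_jitter must lie in [0, 0.5]")
  if (s$muscle_scale < 0)
    stopf("phantom_spec: muscle_scale must be non-negative")
  if (s$hu_lo > s$hu_hi)
    stopf("phantom_spec: hu_lo must not exceed hu_hi")
  invisible(spec)
}

# Base compartment layout in fractional slice coordinates (row, col); row
# grows towards the patient's back (posterior).  Semi-axes for muscles are
# already scaled by muscle_scale.  Jitter multiplies centre offsets (from the
# slice centre) and semi-axes by per-compartment factors fixed per patient.
phantom_geometry <- function(spec, jitter = FALSE) {
  s <- spec$image_size
  m <- spec$muscle_scale
  ell <- function(cr, cc, ar, ac, tissue) {
    list(centre = c(cr, cc) * s, axes = c(ar, ac) * s, tissue = tissue)
  }
  comp <- list(
    body      = ell(0.50, 0.50, spec$body_axes[1] / s, spec$body_axes[2] / s, "fat"),
    vertebra  = ell(0.58, 0.50, 0.070, 0.080, "bone"),
    psoas_l   = ell(0.54, 0.34, 0.070 * m, 0.055 * m, "muscle"),
    psoas_r   = ell(0.54, 0.66, 0.070 * m, 0.055 * m, "muscle"),
    quadratus_l = ell(0.64, 0.27, 0.045 * m, 0.055 * m, "muscle"),
    quadratus_r = ell(0.64, 0.73, 0.045 * m, 0.055 * m, "muscle"),
    paraspinal_l = ell(0.71, 0.41, 0.085 * m, 0.095 * m, "muscle"),
    paraspinal_r = ell(0.71, 0.59, 0.085 * m, 0.095 * m, "muscle"))
  # paraspinal muscles are crescents: the anterior-shifted inner ellipse is
  # carved out of the outer one
  comp$paraspinal_l$inner <- list(centre = c(0.67, 0.41) * s, axes = c(0.055, 0.060) * s * m)
  comp$paraspinal_r$inner <- list(centre = c(0.67, 0.59) * s, axes = c(0.055, 0.060) * s * m)
  if (jitter && spec$per_patient_jitter > 0) {
    j <- spec$per_patient_jitter
    ctr <- s / 2
    for (nm in names(comp)) {
      u <- runif(4, -j, j)
      comp[[nm]]$centre <- ctr + (comp[[nm]]$centre - ctr) * (1 + u[1:2])
      comp[[nm]]$axes <- comp[[nm]]$axes * (1 + u[3:4])
      if (!is.null(comp[[nm]]$inner)) {
        comp[[nm]]$inner$centre <- ctr + (comp[[nm]]$inner$centre - ctr) * (1 + u[1:2])
        comp[[nm]]$inner$axes <- comp[[nm]]$inner$axes * (1 + u[3:4])
      }
    }
  }
  comp
}

inside_ellipse <- function(rows, cols, centre, axes) {
  if (any(axes <= 0)) return(matrix(FALSE, length(rows), length(cols)))
  dr2 <- ((rows - centre[1]) / axes[1])^2
  dc2 <- ((cols - centre[2]) / axes[2])^2
  outer(dr2, dc2, `+`) <= 1
}

#' Generate one synthetic CT slice with its muscle ROI mask
#'
#' Renders the phantom geometry to a label map (air / fat / bone / muscle; the
#' classes are disjoint by construction), draws HU from the per-tissue
#' Gaussians, adds acquisition noise, and quantises to integer HU clamped to
#' `[-1024, 3071]`. The ROI mask is 1 exactly on the union of the six muscle
#' compartments.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed; with the same spec and seed the output is
#'   bit-identical. With `NULL` the current RNG stream is used.
#' @param geometry Optional precomputed geometry (from an internal jitter draw)
#'   so that all slices of one patient share their anatomy.
#' @return A list with `image` (integer HU matrix) and `mask` (0/1 integer
#'   matrix).
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 64), seed = 1)
#' table(ph$mask)
#' @export
generate_phantom <- function(spec, seed = NULL, geometry = NULL) {
  validate_phantom_spec(spec)
  local_seed(seed, {
    if (is.null(geometry)) geometry <- phantom_geometry(spec, jitter = FALSE)
    s <- spec$image_size
    rows <- seq_len(s); cols <- seq_len(s)
    body <- inside_ellipse(rows, cols, geometry$body$centre, geometry$body$axes)
    bone <- inside_ellipse(rows, cols, geometry$vertebra$centre, geometry$vertebra$axes) & body
    muscle <- matrix(FALSE, s, s)
    for (nm in names(geometry)) {
      g <- geometry[[nm]]
      if (!identical(g$tissue, "muscle")) next
      reg <- inside_ellipse(rows, cols, g$centre, g$axes)
      if (!is.null(g$inner)) reg <- reg & !inside_ellipse(rows, cols, g$inner$centre, g$inner$axes)
      muscle <- muscle | reg
    }
    # muscles lie inside a subcutaneous fat rim and are separated from the
    # vertebra by a fascial margin, whatever the jitter draw
    inner_body <- inside_ellipse(rows, cols, geometry$body$centre, geometry$body$axes * 0.94)
    bone_margin <- inside_ellipse(rows, cols, geometry$vertebra$centre,
                                  geometry$vertebra$axes * 1.12)
    muscle <- muscle & inner_body & !bone_margin
    fat <- body & !bone & !muscle
    img <- matrix(spec$air_hu, s, s)
    img[fat] <- rnorm(sum(fat), spec$fat_hu_mean, spec$fat_hu_sd)
    img[bone] <- rnorm(sum(bone), spec$bone_hu_mean, spec$bone_hu_sd)
    img[muscle] <- rnorm(sum(muscle), spec$muscle_hu_mean, spec$muscle_hu_sd)
    if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
    img <- matrix(as.integer(pmin(pmax(round(img), -1024), 3071)), s, s)
    mask <- matrix(0L, s, s)
    mask[muscle] <- 1L
    list(image = img, mask = mask)
  })
}

#' Generate a cohort of synthetic patients
#'
#' Each patient receives one jittered anatomy (per-patient uniform jitter on
#' compartment centres and axes) shared by all of its slices; acquisition noise
#' is redrawn per slice. The default of 4 slices per patient mirrors the two
#' L3 + two L4 cross-sections acquired per subject in routine paravertebral
#' muscle assessment.
#'
#' @param n_patients Number of patients (>= 1).
#' @param spec A [phantom_spec()].
#' @param slices_per_patient Slices per patient (default 4).
#' @param seed Integer seed; the cohort is a pure function of `(spec, seed)`.
#' @return A list of patient records, each `list(patient_id, slices)` where
#'   `slices` is a list of `list(image, mask, patient_id, slice_index)`.
#' @examples
#' coh <- generate_cohort(3, phantom_spec(image_size = 64), seed = 1)
#' length(coh)            # 3 patients
#' length(coh[[1]]$slices)  # 4 slices
#' @export
generate_cohort <- function(n_patients, spec = phantom_spec(),
                            slices_per_patient = 4L, seed = 1L) {
  if (n_patients < 1) stopf("n_patients must be >= 1")
  if (slices_per_patient < 1) stopf("slices_per_patient must be >= 1")
  validate_phantom_spec(spec)
  local_seed(seed, {
    lapply(seq_len(n_patients), function(p) {
      pid <- sprintf("P%04d", p)
      geom <- phantom_geometry(spec, jitter = TRUE)
      slices <- lapply(seq_len(slices_per_patient), function(k) {
        ph <- generate_phantom(spec, seed = NULL, geometry = geom)
        list(image = ph$image, mask = ph$mask, patient_id = pid, slice_index = k)
      })
      list(patient_id = pid, slices = slices)
    })
  })
}

#' Flatten a cohort into a list of slice pairs
#'
#' @param cohort A cohort from [generate_cohort()] (or read back from disk).
#' @param ids Optional character vector of patient ids to keep.
#' @return A flat list of `list(image, mask, patient_id, slice_index)`.
#' @export
cohort_pairs <- function(cohort, ids = NULL) {
  recs <- cohort
  if (!is.null(ids)) recs <- Filter(function(r) r$patient_id %in% ids, recs)
  unlist(lapply(recs, `[[`, "slices"), recursive = FALSE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%d px; muscle %g+/-%g HU; fat %g+/-%g; bone %g+/-%g; air %g; noise sd %g\n",
              x$image_size, x$image_size, x$muscle_hu_mean, x$muscle_hu_sd,
              x$fat_hu_mean, x$fat_hu_sd, x$bone_hu_mean, x$bone_hu_sd,
              x$air_hu, x$noise_sd))
  invisible(x)
}
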