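# Small shared fixtures, all generated in code.

# a fast, small phantom spec used across tests
tiny_spec <- function(size = 64, noise_sd = 10, ...) {
  phantom_spec(image_size = size, noise_sd = noise_sd, ...)
}

# noiseless variant: deterministic tissue HU, no acquisition noise
noiseless_spec <- function(size = 64, muscle = 60) {
  phantom_spec(image_size = size, muscle_hu_mean = muscle, muscle_hu_sd = 0,
               fat_hu_sd = 0, bone_hu_sd = 0, noise_sd = 0)
}

# normalised (image, ground-truth) pairs for patients in a cohort
prep_pairs <- function(cohort, ids = NULL) {
  lapply(cohort_pairs(cohort, ids), function(p) {
    list(image = normalize_hu(p$image),
         mask = apply_hu_filter(p$image, p$mask),
         patient_id = p$patient_id, slice_index = p$slice_index)
  })
}

# independent brute-force Jaccard: enumerate pixels as sets
jaccard_bruteforce <- function(a, b) {
  fa <- which(a == 1)
  fb <- which(b == 1)
  if (length(fa) == 0 && length(fb) == 0) return(1)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

random_mask <- function(h, w, p = 0.5) matrix(rbinom(h * w, 1L, p), h, w)
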