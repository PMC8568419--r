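#' Default run configuration
#'
#' One nested configuration drives every pipeline stage. Defaults are the
#' study protocol: HU window `[-29, 150]`, 6:2:2 patient split, augmentation
#' factor 5, learning rate 1e-4 with Adam, batch size 4, 1000 epochs with
#' patience 100 for both early stopping and learning-rate decay, and 3
#' cross-validation rounds over the `n_base in {16, 32}` x `{DA, no-DA}`
#' grid.
#'
#' @return A nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    phantom = list(image_size = 512L, n_patients = 16L, slices_per_patient = 4L,
                   seed = 1L),
    hu_window = list(lo = -29, hi = 150),
    split = list(ratios = c(0.6, 0.2, 0.2), seed = 1L),
    augment = list(factor = 5L, max_shift = 0.05, max_angle = 20, seed = 1L),
    unet = list(n_base = 32L, depth = 5L, leaky_slope = 0.01, seed = 1L),
    train = list(lr = 1e-4, batch_size = 4L, max_epochs = 1000L,
                 early_stop_patience = 100L, lr_decay_patience = 100L,
                 lr_decay_factor = 0.1, seed = 1L),
    cv = list(n_rounds = 3L, seeds = c(101L, 202L, 303L)),
    out = "paraseg_run")
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills unspecified fields with the
#' protocol defaults, and checks every cross-field invariant: split ratios
#' summing to 1, the image side divisible by `2^(depth-1)`, an ordered HU
#' window, positive counts, distinct cross-validation seeds, and a seed for
#' every random stage. Violations are reported with the offending field.
#'
#' @param config Path to a YAML file, or a (possibly partial) nested list.
#' @return The completed configuration list, classed `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stopf("config must be a file path or a list")
  cfg <- merge_config(default_run_config(), config)

  if (abs(sum(cfg$split$ratios) - 1) > 1e-9)
    stopf("config split$ratios must sum to 1 (got %.12g)", sum(cfg$split$ratios))
  if (length(cfg$split$ratios) != 3L)
    stopf("config split$ratios must have 3 entries")
  if (cfg$hu_window$lo > cfg$hu_window$hi)
    stopf("config hu_window: lo (%g) exceeds hi (%g)", cfg$hu_window$lo, cfg$hu_window$hi)
  if (cfg$phantom$image_size %% 2^(cfg$unet$depth - 1) != 0)
    stopf("config: image_size %d not divisible by 2^(depth-1) = %d",
          cfg$phantom$image_size, 2^(cfg$unet$depth - 1))
  if (cfg$augment$factor < 1) stopf("config augment$factor must be >= 1")
  if (cfg$augment$max_shift < 0 || cfg$augment$max_shift > 0.5)
    stopf("config augment$max_shift out of range")
  if (cfg$cv$n_rounds > length(unique(cfg$cv$seeds)))
    stopf("config cv: need %d distinct seeds, got %d",
          cfg$cv$n_rounds, length(unique(cfg$cv$seeds)))
  for (sec in c("phantom", "split", "augment", "unet", "train"))
    if (is.null(cfg[[sec]]$seed)) stopf("config %s$seed is missing", sec)
  # these constructors re-validate their own fields
  train_config(lr = cfg$train$lr, batch_size = cfg$train$batch_size,
               max_epochs = cfg$train$max_epochs,
               early_stop_patience = cfg$train$early_stop_patience,
               lr_decay_patience = cfg$train$lr_decay_patience,
               lr_decay_factor = cfg$train$lr_decay_factor,
               seed = cfg$train$seed)
  unet_config(n_base = cfg$unet$n_base, depth = cfg$unet$depth,
              leaky_slope = cfg$unet$leaky_slope)
  structure(cfg, class = "run_config")
}
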