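#' Jaccard score (intersection over union) between two binary masks
#'
#' `|pred & gt| / |pred | gt|` over foreground pixels. When both masks are
#' empty the score is defined as 1: perfect agreement on an empty slice is
#' not penalised. This convention affects per-image averages and is applied
#' consistently throughout the package.
#'
#' @param pred,gt Binary 0/1 matrices of equal shape.
#' @return Score in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2)
#' b <- matrix(c(0, 1, 1, 0), 2, 2)
#' jaccard(a, b)  # 1/3
#' @export
jaccard <- function(pred, gt) {
  check_same_shape(pred, gt, "pred", "gt")
  if (!is_binary_mask(pred) || !is_binary_mask(gt))
    stopf("jaccard requires binary 0/1 masks")
  inter <- sum(pred == 1L & gt == 1L)
  uni <- sum(pred == 1L | gt == 1L)
  if (uni == 0L) 1 else inter / uni
}

#' Pixel confusion counts between prediction and ground truth
#'
#' @inheritParams jaccard
#' @return Named integer vector `c(tp, fp, fn, tn)`; the four counts sum to
#'   the pixel count, and `jaccard = tp / (tp + fp + fn)` whenever that
#'   denominator is positive.
#' @export
confusion_counts <- function(pred, gt) {
  check_same_shape(pred, gt, "pred", "gt")
  if (!is_binary_mask(pred) || !is_binary_mask(gt))
    stopf("confusion_counts requires binary 0/1 masks")
  c(tp = sum(pred == 1L & gt == 1L), fp = sum(pred == 1L & gt == 0L),
    fn = sum(pred == 0L & gt == 1L), tn = sum(pred == 0L & gt == 0L))
}

#' Render a TP/FN/FP overlay
#'
#' True positives are white, false negatives green, false positives red and
#' true negatives black — the conventional error-visualisation palette for
#' segmentation masks.
#'
#' @inheritParams jaccard
#' @return An `H x W x 3` RGB array in `[0, 1]` with attribute `counts`
#'   (from [confusion_counts()]). Write with `png::writePNG()`.
#' @export
confusion_map <- function(pred, gt) {
  counts <- confusion_counts(pred, gt)
  H <- nrow(pred); W <- ncol(pred)
  rgb <- array(0, dim = c(H, W, 3))
  tp <- pred == 1L & gt == 1L
  fn <- pred == 0L & gt == 1L
  fp <- pred == 1L & gt == 0L
  r <- matrix(0, H, W); g <- matrix(0, H, W); b <- matrix(0, H, W)
  r[tp | fp] <- 1
  g[tp | fn] <- 1
  b[tp] <- 1
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  attr(rgb, "counts") <- counts
  rgb
}

#' Score a model on a set of slice pairs
#'
#' @param net A trained `unet`.
#' @param pairs List of `list(image, mask, ...)` with normalised images.
#' @return An `eval_result`: list with `per_image` (data frame of per-slice
#'   Jaccard and confusion counts), `mean_jaccard`, `sd_jaccard` (sd across
#'   slices).
#' @export
evaluate_pairs <- function(net, pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    pred <- unet_predict(net, p$image)$mask
    cc <- confusion_counts(pred, p$mask)
    data.frame(index = i,
               patient_id = if (is.null(p$patient_id)) NA_character_ else p$patient_id,
               jaccard = jaccard(pred, p$mask),
               tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]], tn = cc[["tn"]],
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 mean_jaccard = mean(per_image$jaccard),
                 sd_jaccard = if (nrow(per_image) > 1) sd(per_image$jaccard) else 0),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: mean Jaccard %.4f +/- %.4f over %d slices\n",
              x$mean_jaccard, x$sd_jaccard, nrow(x$per_image)))
  invisible(x)
}

#' Repeated holdout cross-validation over the model grid
#'
#' Each round draws a fresh seeded patient-level 60/20/20 split, builds the
#' HU-filtered ground truth, optionally augments the training slices, trains
#' every model in the grid from a fresh initialisation, and scores the
#' foreground Jaccard on that round's held-out test slices. The final score
#' per model is the unweighted arithmetic mean of its round scores; the
#' selected model maximises the final score, with the lower across-round
#' standard deviation breaking ties (stability preferred).
#'
#' @param cohort A cohort (>= 5 patients) of raw-HU slice/ROI records.
#' @param model_grid Data frame with columns `n_base` (filters at level 1)
#'   and `augment` (logical: apply CT-aware augmentation); defaults to the
#'   2 x 2 grid `n_base in {16, 32}` with and without augmentation.
#' @param n_rounds Number of independent holdout rounds (default 3).
#' @param seeds Integer vector of distinct per-round seeds, length
#'   `>= n_rounds`.
#' @param depth U-Net depth used for every model.
#' @param train_cfg A [train_config()].
#' @param augment_factor Expansion factor when `augment` is TRUE.
#' @param hu_lo,hu_hi Ground-truth HU window.
#' @param ratios Split ratios.
#' @param verbose Print progress.
#' @return A `cv_report`: list with `rounds` (per-round data frames), `final`
#'   (per-model mean/sd across rounds) and `selected_model`.
#' @export
run_cv <- function(cohort,
                   model_grid = data.frame(n_base = c(16L, 32L, 16L, 32L),
                                           augment = c(TRUE, TRUE, FALSE, FALSE)),
                   n_rounds = 3L, seeds = c(101L, 202L, 303L),
                   depth = 5L, train_cfg = train_config(),
                   augment_factor = 5L, hu_lo = -29, hu_hi = 150,
                   ratios = c(0.6, 0.2, 0.2), verbose = FALSE) {
  if (length(cohort) < 5) stopf("run_cv needs a cohort of at least 5 patients")
  if (length(unique(seeds)) < n_rounds)
    stopf("run_cv needs %d distinct seeds (got %d)", n_rounds, length(unique(seeds)))
  if (nrow(model_grid) < 1) stopf("model grid is empty")
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  prep <- function(pairs) {
    lapply(pairs, function(p) {
      gt <- apply_hu_filter(p$image, p$mask, hu_lo, hu_hi)
      list(image = p$image, mask = gt, patient_id = p$patient_id,
           slice_index = p$slice_index)
    })
  }
  normalize_pairs <- function(pairs) {
    lapply(pairs, function(p) { p$image <- normalize_hu(p$image); p })
  }
  rounds <- vector("list", n_rounds)
  splits <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    sp <- split_by_patient(ids, ratios, seed = seeds[r])
    splits[[r]] <- sp
    tr <- prep(cohort_pairs(cohort, sp$train))
    va <- normalize_pairs(prep(cohort_pairs(cohort, sp$val)))
    te <- normalize_pairs(prep(cohort_pairs(cohort, sp$test)))
    res <- lapply(seq_len(nrow(model_grid)), function(m) {
      nb <- model_grid$n_base[m]
      da <- isTRUE(model_grid$augment[m])
      tr_m <- if (da) augment_dataset(tr, factor = augment_factor,
                                      seed = seeds[r] + 7L * m) else tr
      tr_m <- normalize_pairs(tr_m)
      side <- nrow(tr_m[[1]]$image)
      net <- build_unet(unet_config(n_base = nb, depth = depth),
                        input_size = side, seed = seeds[r] + 1000L * m)
      cfg <- train_cfg
      cfg$seed <- seeds[r] + 31L * m
      fit <- train_unet(net, tr_m, va, cfg)
      ev <- evaluate_pairs(fit$net, te)
      if (verbose)
        message(sprintf("round %d model n_base=%d DA=%s: test Jaccard %.4f",
                        r, nb, da, ev$mean_jaccard))
      data.frame(round = r, n_base = nb, augment = da,
                 jaccard_mean = ev$mean_jaccard, jaccard_sd = ev$sd_jaccard,
                 best_epoch = fit$best_epoch, stringsAsFactors = FALSE)
    })
    rounds[[r]] <- do.call(rbind, res)
  }
  all_rounds <- do.call(rbind, rounds)
  key <- interaction(all_rounds$n_base, all_rounds$augment, drop = TRUE)
  final <- do.call(rbind, lapply(split(all_rounds, key), function(d) {
    data.frame(n_base = d$n_base[1], augment = d$augment[1],
               final_jaccard = mean(d$jaccard_mean),
               round_sd = if (nrow(d) > 1) sd(d$jaccard_mean) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(final) <- NULL
  ord <- order(-final$final_jaccard, final$round_sd)
  sel <- final[ord[1], ]
  structure(list(rounds = rounds, all_rounds = all_rounds, final = final,
                 selected_model = sel, splits = splits, seeds = seeds[seq_len(n_rounds)]),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Holdout cross-validation report\n")
  print(x$final)
  cat(sprintf("selected: n_base=%d, augmentation=%s (final Jaccard %.4f)\n",
              x$selected_model$n_base, x$selected_model$augment,
              x$selected_model$final_jaccard))
  invisible(x)
}
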