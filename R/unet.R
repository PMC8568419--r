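#' U-Net architecture configuration
#'
#' The encoder has `depth` levels of two same-padded 3x3 convolutions with
#' leaky-ReLU activation, separated by 2x2 max pooling with stride 2; the
#' number of filters at level `i` follows the geometric rule
#' `n_base * 2^(i-1)`. The decoder mirrors the encoder with 2x2 transposed
#' convolutions (stride 2) and skip concatenation from the matching encoder
#' level, and the head is a 1x1 convolution to `n_classes` followed by a
#' per-pixel softmax.
#'
#' @param n_base Filters in the first convolutional level (the study grid
#'   uses 16 and 32; 32 is the default initial channel number).
#' @param depth Number of encoder levels `L` (>= 2); the input side must be
#'   divisible by `2^(depth-1)`.
#' @param in_channels Input channels (1 for grayscale CT).
#' @param n_classes Output classes (2: background/muscle).
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @param norm Per-channel feature normalisation after each 3x3 convolution:
#'   `"none"` (default, the plain architecture) or `"instance"`
#'   (per-sample, per-channel standardisation with learned gain/offset).
#'   Instance normalisation is batch-size independent and greatly accelerates
#'   optimisation when the step budget is small.
#' @return A `unet_config` object.
#' @export
unet_config <- function(n_base = 32L, depth = 5L, in_channels = 1L,
                        n_classes = 2L, leaky_slope = 0.01,
                        norm = c("none", "instance")) {
  norm <- match.arg(norm)
  if (n_base < 1) stopf("unet_config: n_base must be >= 1")
  if (depth < 2) stopf("unet_config: depth must be >= 2")
  if (in_channels < 1 || n_classes < 2) stopf("unet_config: bad channel counts")
  if (leaky_slope < 0 || leaky_slope >= 1) stopf("unet_config: leaky_slope must be in [0, 1)")
  structure(list(n_base = as.integer(n_base), depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), leaky_slope = leaky_slope,
                 norm = norm),
            class = "unet_config")
}

#' Filters at a given encoder level
#'
#' Implements the geometric filter-scaling rule `n_base * 2^(i-1)` for level
#' `i = 1, 2, ..., L`.
#'
#' @param n_base Filters in the first level (>= 1).
#' @param level Level index `i` (>= 1).
#' @return Integer filter count.
#' @examples
#' filters_for_level(16, 1)  # 16
#' filters_for_level(16, 4)  # 128
#' @export
filters_for_level <- function(n_base, level) {
  if (any(level < 1)) stopf("level index must be >= 1")
  if (n_base < 1) stopf("n_base must be >= 1")
  as.integer(n_base * 2^(level - 1))
}

check_input_side <- function(side, depth) {
  if (side %% 2^(depth - 1) != 0)
    stopf("input side %d is not divisible by 2^(depth-1) = %d; pooling would not be exact",
          side, 2^(depth - 1))
  invisible(side)
}

he_uniform <- function(n_out, fan_in_cols) {
  lim <- sqrt(6 / fan_in_cols)
  matrix(runif(n_out * fan_in_cols, -lim, lim), n_out, fan_in_cols)
}

#' Build (initialise) a U-Net
#'
#' Allocates all convolution weights with seeded He-uniform initialisation
#' (`limit = sqrt(6 / fan_in)`) and zero biases.
#'
#' @param config A [unet_config()].
#' @param input_size Optional input side for early validation against
#'   `2^(depth-1)` divisibility (also re-checked at every forward pass).
#' @param seed Integer seed for the weight draw.
#' @return A `unet` object (config plus parameter list).
#' @export
build_unet <- function(config, input_size = NULL, seed = 1L) {
  if (!inherits(config, "unet_config")) stopf("config must be a unet_config")
  if (!is.null(input_size)) check_input_side(input_size, config$depth)
  L <- config$depth
  use_norm <- config$norm == "instance"
  conv_p <- function(f, fan) {
    p <- list(w = he_uniform(f, fan), b = numeric(f))
    if (use_norm) { p$gamma <- rep(1, f); p$beta <- numeric(f) }
    p
  }
  local_seed(seed, {
    enc <- vector("list", L)
    cin <- config$in_channels
    for (i in seq_len(L)) {
      f <- filters_for_level(config$n_base, i)
      enc[[i]] <- list(conv1 = conv_p(f, cin * 9), conv2 = conv_p(f, f * 9))
      cin <- f
    }
    dec <- vector("list", L - 1)
    for (i in rev(seq_len(L - 1))) {
      f <- filters_for_level(config$n_base, i)
      f_up <- filters_for_level(config$n_base, i + 1)
      dec[[i]] <- list(
        up = list(w = he_uniform(f, f_up * 4), b = numeric(f)),
        conv1 = conv_p(f, 2 * f * 9),
        conv2 = conv_p(f, f * 9))
    }
    head <- list(w = he_uniform(config$n_classes, config$n_base), b = numeric(config$n_classes))
    structure(list(config = config, params = list(enc = enc, dec = dec, head = head)),
              class = "unet")
  })
}

#' Number of trainable parameters
#' @param net A `unet`.
#' @return Integer count of weights and biases.
#' @export
n_params <- function(net) {
  sum(rapply(net$params, length, how = "unlist"))
}

#' Filters per level recovered from the built network
#'
#' Introspects the weight shapes so tests can confirm the built network obeys
#' the `n_base * 2^(i-1)` rule.
#'
#' @param net A `unet`.
#' @return Integer vector of length `depth`.
#' @export
unet_level_filters <- function(net) {
  vapply(net$params$enc, function(lv) nrow(lv$conv1$w), integer(1))
}

as_input_cube <- function(x, in_channels) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  if (dim(x)[3] != in_channels) stopf("expected %d input channel(s)", in_channels)
  x
}

# one [3x3 conv -> (instance norm) -> leaky ReLU] unit; with norm off the
# activation is fused into the convolution kernel call
conv_block_fw <- function(x, pp, slope, use_norm) {
  if (!use_norm) {
    y <- cpp_conv_fw(x, pp$w, pp$b, TRUE, slope)
    return(list(y = y))
  }
  z <- cpp_conv_fw(x, pp$w, pp$b, FALSE, 0)
  nf <- cpp_inorm_fw(z, pp$gamma, pp$beta, 1e-5)
  list(y = cpp_lrelu_fw(nf$y, slope), conv_out = z,
       xhat = nf$xhat, inv_sd = nf$inv_sd)
}

conv_block_bw <- function(x, pp, blk, gy, slope, use_norm) {
  if (!use_norm) {
    cb <- cpp_conv_bw(x, pp$w, blk$y, gy, TRUE, slope)
    return(list(gx = cb$gx, g = list(w = cb$gw, b = as.numeric(cb$gb))))
  }
  gnorm_out <- cpp_lrelu_bw(blk$y, gy, slope)
  nb <- cpp_inorm_bw(blk$xhat, blk$inv_sd, pp$gamma, gnorm_out)
  cb <- cpp_conv_bw(x, pp$w, blk$conv_out, nb$gx, FALSE, 0)
  list(gx = cb$gx,
       g = list(w = cb$gw, b = as.numeric(cb$gb),
                gamma = as.numeric(nb$ggamma), beta = as.numeric(nb$gbeta)))
}

#' Forward pass
#'
#' @param net A `unet`.
#' @param x Normalised input, a matrix or `H x W x in_channels` array; the
#'   side must be square and divisible by `2^(depth-1)`.
#' @param train Keep intermediate activations for backpropagation.
#' @return List with `prob` (`H x W x n_classes`, per-pixel softmax summing to
#'   1), `logits`, and (if `train`) a `cache` of activations.
#' @export
unet_forward <- function(net, x, train = FALSE) {
  cfg <- net$config
  x <- as_input_cube(x, cfg$in_channels)
  if (dim(x)[1] != dim(x)[2]) stopf("input must be square")
  check_input_side(dim(x)[1], cfg$depth)
  L <- cfg$depth
  sl <- cfg$leaky_slope
  un <- cfg$norm == "instance"
  cache <- list(enc_in = vector("list", L), enc1 = vector("list", L),
                enc2 = vector("list", L), pool_idx = vector("list", L - 1),
                dec = vector("list", L - 1))
  cur <- x
  for (i in seq_len(L)) {
    cache$enc_in[[i]] <- cur
    blk1 <- conv_block_fw(cur, net$params$enc[[i]]$conv1, sl, un)
    cache$enc1[[i]] <- blk1
    blk2 <- conv_block_fw(blk1$y, net$params$enc[[i]]$conv2, sl, un)
    cache$enc2[[i]] <- blk2
    if (i < L) {
      pl <- cpp_pool_fw(blk2$y)
      cache$pool_idx[[i]] <- pl$idx
      cur <- pl$y
    } else cur <- blk2$y
  }
  for (i in rev(seq_len(L - 1))) {
    d <- net$params$dec[[i]]
    up <- cpp_upconv_fw(cur, d$up$w, d$up$b)
    skip <- cache$enc2[[i]]$y
    cat_in <- array(c(skip, up), dim = c(dim(up)[1], dim(up)[2], dim(skip)[3] + dim(up)[3]))
    blk1 <- conv_block_fw(cat_in, d$conv1, sl, un)
    blk2 <- conv_block_fw(blk1$y, d$conv2, sl, un)
    cache$dec[[i]] <- list(up_in = cur, up = up, cat_in = cat_in,
                           b1 = blk1, b2 = blk2)
    cur <- blk2$y
  }
  logits <- cpp_conv_fw(cur, net$params$head$w, net$params$head$b, FALSE, 0)
  # numerically stable per-pixel softmax over the class slices
  nc <- dim(logits)[3]
  mx <- logits[, , 1]
  for (ci in seq_len(nc)[-1]) mx <- pmax(mx, logits[, , ci])
  e <- logits
  tot <- 0
  for (ci in seq_len(nc)) { e[, , ci] <- exp(logits[, , ci] - mx); tot <- tot + e[, , ci] }
  prob <- e
  for (ci in seq_len(nc)) prob[, , ci] <- e[, , ci] / tot
  out <- list(prob = prob, logits = logits)
  if (train) { cache$head_in <- cur; out$cache <- cache }
  out
}

# Backward pass for softmax + pixel-mean cross-entropy against a 0/1 mask.
# Returns the loss and a gradient list mirroring net$params.
unet_backward <- function(net, fwd, gt) {
  cfg <- net$config
  L <- cfg$depth
  sl <- cfg$leaky_slope
  un <- cfg$norm == "instance"
  cache <- fwd$cache
  npix <- length(gt)
  p1 <- fwd$prob[, , 2]
  p_true <- ifelse(gt == 1L, p1, fwd$prob[, , 1])
  loss <- -mean(log(pmax(p_true, 1e-12)))
  glog <- fwd$prob
  glog[, , 1] <- (glog[, , 1] - (gt == 0L)) / npix
  glog[, , 2] <- (glog[, , 2] - (gt == 1L)) / npix
  g <- list(enc = vector("list", L), dec = vector("list", L - 1), head = NULL)
  skip_g <- vector("list", L - 1)
  bh <- cpp_conv_bw(cache$head_in, net$params$head$w, fwd$logits, glog, FALSE, 0)
  g$head <- list(w = bh$gw, b = as.numeric(bh$gb))
  gcur <- bh$gx
  for (i in seq_len(L - 1)) {
    d <- net$params$dec[[i]]
    dc <- cache$dec[[i]]
    b2g <- conv_block_bw(dc$b1$y, d$conv2, dc$b2, gcur, sl, un)
    b1g <- conv_block_bw(dc$cat_in, d$conv1, dc$b1, b2g$gx, sl, un)
    nskip <- dim(cache$enc2[[i]]$y)[3]
    skip_g[[i]] <- b1g$gx[, , seq_len(nskip), drop = FALSE]
    g_up <- b1g$gx[, , nskip + seq_len(dim(dc$up)[3]), drop = FALSE]
    upg <- cpp_upconv_bw(dc$up_in, d$up$w, g_up)
    g$dec[[i]] <- list(up = list(w = upg$gw, b = as.numeric(upg$gb)),
                       conv1 = b1g$g, conv2 = b2g$g)
    gcur <- upg$gx
  }
  for (i in rev(seq_len(L))) {
    e <- net$params$enc[[i]]
    if (i < L) {
      # gradient arriving from the pooled path plus the skip connection
      hw <- dim(cache$enc2[[i]]$y)[1]
      gout <- cpp_pool_bw(cache$pool_idx[[i]], gcur, hw, hw) + skip_g[[i]]
    } else gout <- gcur
    c2g <- conv_block_bw(cache$enc1[[i]]$y, e$conv2, cache$enc2[[i]], gout, sl, un)
    c1g <- conv_block_bw(cache$enc_in[[i]], e$conv1, cache$enc1[[i]], c2g$gx, sl, un)
    g$enc[[i]] <- list(conv1 = c1g$g, conv2 = c2g$g)
    gcur <- c1g$gx
  }
  list(loss = loss, grads = g)
}

#' Segment one slice
#'
#' Runs the forward pass and takes the per-pixel argmax over the softmax
#' channels. Exact probability ties go to the background class, a
#' deterministic and conservative convention. The input must already be
#' normalised to `[0, 1]` (see [normalize_hu()]); raw HU input is rejected.
#'
#' @param net A `unet`.
#' @param image Normalised input matrix.
#' @return List with `prob` (`H x W x 2`) and `mask` (0/1 integer matrix).
#' @export
unet_predict <- function(net, image) {
  if (min(image) < -1e-6 || max(image) > 1 + 1e-6)
    stopf("input does not look normalised to [0, 1] (range %.3g..%.3g); apply normalize_hu() first",
          min(image), max(image))
  fwd <- unet_forward(net, image, train = FALSE)
  mask <- matrix(as.integer(fwd$prob[, , 2] > fwd$prob[, , 1]),
                 dim(fwd$prob)[1], dim(fwd$prob)[2])
  list(prob = fwd$prob, mask = mask)
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf("unet: depth %d, n_base %d, filters %s, %d parameters\n",
              x$config$depth, x$config$n_base,
              paste(unet_level_filters(x), collapse = "/"), n_params(x)))
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the architecture configuration so a loaded network
#' is self-describing.
#'
#' @param net A `unet`.
#' @param path File path.
#' @export
unet_save <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname unet_save
#' @export
unet_load <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "unet")) stopf("not a unet checkpoint: %s", path)
  net
}
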