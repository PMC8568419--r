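test_that("filter-scaling rule n_base * 2^(i-1)", {
  expect_equal(filters_for_level(16, 1), 16L)
  expect_equal(filters_for_level(16, 4), 128L)
  expect_equal(filters_for_level(32, 3), 128L)
  expect_equal(filters_for_level(16, 5), 256L)
  expect_equal(filters_for_level(32, 5), 512L)
  expect_error(filters_for_level(16, 0), "level")
  expect_error(filters_for_level(0, 1), "n_base")
})

test_that("built networks expose the filter rule at every level", {
  for (nb in c(2L, 3L)) {
    net <- build_unet(unet_config(n_base = nb, depth = 3), seed = 1)
    expect_identical(unet_level_filters(net), filters_for_level(nb, 1:3))
  }
})

test_that("minimal network runs and preserves spatial shape with unit softmax sums", {
  net <- build_unet(unet_config(n_base = 2, depth = 2), seed = 1)
  x <- matrix(runif(64), 8, 8)
  out <- unet_forward(net, x)
  expect_equal(dim(out$prob), c(8, 8, 2))
  expect_lt(max(abs(out$prob[, , 1] + out$prob[, , 2] - 1)), 1e-5)
})

test_that("output shape equals input shape for random valid sizes and depths", {
  set.seed(2)
  for (i in 1:5) {
    depth <- sample(2:4, 1)
    side <- 2^(depth - 1) * sample(2:4, 1)
    net <- build_unet(unet_config(n_base = 2, depth = depth), seed = i)
    out <- unet_forward(net, matrix(runif(side^2), side, side))
    expect_equal(dim(out$prob)[1:2], c(side, side))
    expect_lt(max(abs(out$prob[, , 1] + out$prob[, , 2] - 1)), 1e-5)
  }
})

test_that("indivisible input sides are rejected", {
  expect_error(build_unet(unet_config(n_base = 2, depth = 5), input_size = 100),
               "divisible")
  net <- build_unet(unet_config(n_base = 2, depth = 3), seed = 1)
  expect_error(unet_forward(net, matrix(0.5, 10, 10)), "divisible")
  expect_error(unet_forward(net, matrix(0.5, 8, 12)), "square")
})

test_that("parameter count strictly increases with n_base at fixed depth", {
  n16 <- n_params(build_unet(unet_config(n_base = 16, depth = 5), seed = 1))
  n32 <- n_params(build_unet(unet_config(n_base = 32, depth = 5), seed = 1))
  expect_gt(n32, n16)
})

test_that("prediction is a binary argmax with background winning exact ties", {
  net <- build_unet(unet_config(n_base = 2, depth = 2), seed = 4)
  pred <- unet_predict(net, matrix(runif(64), 8, 8))
  expect_true(all(pred$mask %in% c(0L, 1L)))
  # zero weights duplicate both class channels exactly: every pixel ties
  net0 <- net
  net0$params <- rapply(net0$params, function(x) x * 0, how = "replace")
  pred0 <- unet_predict(net0, matrix(runif(64), 8, 8))
  expect_true(all(pred0$mask == 0L))
})

test_that("raw-HU (unnormalised) input is rejected at prediction time", {
  net <- build_unet(unet_config(n_base = 2, depth = 2), seed = 1)
  expect_error(unet_predict(net, matrix(c(-1000, 200), 8, 8)), "normalis")
})

test_that("initialisation is seeded and deterministic", {
  a <- build_unet(unet_config(n_base = 2, depth = 3), seed = 11)
  b <- build_unet(unet_config(n_base = 2, depth = 3), seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, build_unet(unet_config(n_base = 2, depth = 3), seed = 12)))
})

test_that("analytic gradients match central finite differences on a tiny net", {
  set.seed(42)
  img <- matrix(runif(64), 8, 8)
  gt <- matrix(rbinom(64, 1L, 0.4), 8, 8)
  net <- build_unet(unet_config(n_base = 2, depth = 2), seed = 3)
  fwd <- unet_forward(net, img, train = TRUE)
  bk <- paraseg:::unet_backward(net, fwd, gt)
  loss_at <- function(n) {
    f <- unet_forward(n, img)
    -mean(log(pmax(ifelse(gt == 1L, f$prob[, , 2], f$prob[, , 1]), 1e-12)))
  }
  eps <- 1e-6
  pluck_get <- function(x, path) Reduce(`[[`, path, x)
  pluck_add <- function(x, path, i, delta) {
    if (length(path) == 1) { x[[path[[1]]]][i] <- x[[path[[1]]]][i] + delta; return(x) }
    x[[path[[1]]]] <- pluck_add(x[[path[[1]]]], path[-1], i, delta)
    x
  }
  paths <- list(
    list("enc", 1L, "conv1", "w"), list("enc", 2L, "conv2", "w"),
    list("dec", 1L, "up", "w"), list("dec", 1L, "conv1", "w"),
    list("head", "w"), list("enc", 1L, "conv2", "b"))
  for (path in paths) {
    g <- pluck_get(bk$grads, path)
    w <- pluck_get(net$params, path)
    for (i in sample(length(w), min(3, length(w)))) {
      np <- net; np$params <- pluck_add(np$params, path, i, eps)
      nm <- net; nm$params <- pluck_add(nm$params, path, i, -eps)
      num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
      expect_equal(num, g[i], tolerance = 1e-4)
    }
  }
})

test_that("instance-normalised variant: valid softmax, exact gradients, learnable", {
  set.seed(7)
  img <- matrix(runif(64), 8, 8)
  gt <- matrix(rbinom(64, 1L, 0.4), 8, 8)
  net <- build_unet(unet_config(n_base = 2, depth = 2, norm = "instance"), seed = 2)
  out <- unet_forward(net, img, train = TRUE)
  expect_lt(max(abs(out$prob[, , 1] + out$prob[, , 2] - 1)), 1e-5)
  bk <- paraseg:::unet_backward(net, out, gt)
  loss_at <- function(n) {
    f <- unet_forward(n, img)
    -mean(log(pmax(ifelse(gt == 1L, f$prob[, , 2], f$prob[, , 1]), 1e-12)))
  }
  eps <- 1e-6
  for (i in 1:3) {
    np <- net; np$params$enc[[1]]$conv1$gamma[1] <- np$params$enc[[1]]$conv1$gamma[1] + eps
    nm <- net; nm$params$enc[[1]]$conv1$gamma[1] <- nm$params$enc[[1]]$conv1$gamma[1] - eps
    expect_equal((loss_at(np) - loss_at(nm)) / (2 * eps),
                 bk$grads$enc[[1]]$conv1$gamma[1], tolerance = 1e-4)
    np <- net; np$params$dec[[1]]$conv2$w[i] <- np$params$dec[[1]]$conv2$w[i] + eps
    nm <- net; nm$params$dec[[1]]$conv2$w[i] <- nm$params$dec[[1]]$conv2$w[i] - eps
    expect_equal((loss_at(np) - loss_at(nm)) / (2 * eps),
                 bk$grads$dec[[1]]$conv2$w[i], tolerance = 1e-4)
  }
  # gamma/beta present exactly when norm is on
  expect_null(build_unet(unet_config(n_base = 2, depth = 2), seed = 1)$params$enc[[1]]$conv1$gamma)
  expect_length(net$params$enc[[2]]$conv2$gamma, 4)
})

test_that("checkpoints round-trip through save/load with their config", {
  net <- build_unet(unet_config(n_base = 2, depth = 2), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  unet_save(net, path)
  expect_identical(unet_load(path), net)
})
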