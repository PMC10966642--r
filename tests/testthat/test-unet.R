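small_net <- function(k = 3, S = 64L, seed = 1L, dropout = 0) {
  build_unet(network_config(base_filters = 8, max_filters = 32,
                            dropout_rate = dropout), k = k, S = S, seed = seed)
}

test_that("the network maps (S, k+3) inputs to (S, 3) outputs in (-1, 1)", {
  for (k in c(3L, 4L, 6L)) {
    m <- small_net(k = k)
    x <- array(rnorm(2 * 64 * (k + 3), sd = 0.3), c(2, 64, k + 3))
    y <- unet_forward(m, x)
    expect_equal(dim(y), c(2L, 64L, 3L))
    expect_true(all(abs(y) < 1))
  }
  # reference geometry: five stride-2 halvings of 1024 give 32
  expect_equal(1024 / 2^5, 32)
  expect_error(build_unet(network_config(), k = 3, S = 48),
               "not divisible")
})

test_that("evaluation mode is deterministic and order-preserving", {
  m <- small_net(dropout = 0.5)   # dropout must be inert in eval mode
  set.seed(2)
  x <- array(rnorm(4 * 64 * 6, sd = 0.3), c(4, 64, 6))
  y1 <- unet_forward(m, x)
  y2 <- unet_forward(m, x)
  expect_identical(y1, y2)
  # batch order preserved: single-sample forward equals its batch slice
  y_single <- unet_forward(m, x[3, , ])
  expect_equal(y_single, y1[3, , ], tolerance = 1e-12)
  # zero input stays finite
  y0 <- unet_forward(m, array(0, c(1, 64, 6)))
  expect_true(all(is.finite(y0)))
  expect_error(unet_forward(m, array(0, c(1, 32, 6))), "input must be")
})

test_that("parameter count is a pure function of the configuration", {
  m1 <- small_net(seed = 1)
  m2 <- small_net(seed = 99)
  expect_equal(count_parameters(m1), count_parameters(m2))
  # frozen regression value for this small reference configuration
  expect_equal(count_parameters(m1), 29395L)
  # reference architecture (64..512 filters, k = 3): frozen count
  big <- build_unet(network_config(), k = 3, S = 1024, seed = 1)
  expect_equal(count_parameters(big), 4201859L)
})

test_that("checkpoints roundtrip bitwise and validate their metadata", {
  m <- small_net()
  sc <- codec_scales(s = 6)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path, metadata = list(scales = sc,
                                           composition = "homopolymer",
                                           note = "probe"))
  ck <- load_checkpoint(path)
  expect_identical(ck$metadata$note, "probe")
  expect_identical(ck$metadata$composition, "homopolymer")
  set.seed(3)
  x <- array(rnorm(2 * 64 * 6, sd = 0.2), c(2, 64, 6))
  expect_identical(unet_forward(ck$model, x), unet_forward(m, x))
  expect_error(load_checkpoint(path, expected_k = 4), "k = 3")
  expect_error(save_checkpoint(m, path, metadata = list()), "metadata")
})

test_that("network gradients match finite differences", {
  m <- small_net(S = 32L)
  B <- 2
  set.seed(7)
  x <- array(rnorm(B * 32 * 6, sd = 0.3), c(B, 32, 6))
  Xm <- plabackmap:::.batch_to_mat(x)
  R <- matrix(rnorm(B * 32 * 3), B * 32, 3)
  fwd <- plabackmap:::.unet_forward_mat(m, Xm, B, training = TRUE)
  g <- plabackmap:::.unet_backward_mat(fwd$model, fwd$caches, R)
  lossf <- function(mm) sum(plabackmap:::.unet_forward_mat(mm, Xm, B, training = TRUE)$Y * R)
  eps <- 1e-5
  probes <- list(
    list(get = function(mm) mm$encoder[[1]]$conv$W,
         set = function(mm, w) { mm$encoder[[1]]$conv$W[] <- w; mm },
         grad = g$encoder[[1]]$conv$dW),
    list(get = function(mm) mm$decoder[[2]]$tconv$W,
         set = function(mm, w) { mm$decoder[[2]]$tconv$W[] <- w; mm },
         grad = g$decoder[[2]]$tconv$dW),
    list(get = function(mm) mm$encoder[[3]]$bn$beta,
         set = function(mm, w) { mm$encoder[[3]]$bn$beta[] <- w; mm },
         grad = g$encoder[[3]]$bn$dbeta),
    list(get = function(mm) mm$final$W,
         set = function(mm, w) { mm$final$W[] <- w; mm },
         grad = g$final$dW))
  set.seed(8)
  for (p in probes) {
    w <- p$get(m)
    for (ix in sample(length(w), 2)) {
      f1 <- lossf(p$set(m, replace(w, ix, w[ix] + eps)))
      f2 <- lossf(p$set(m, replace(w, ix, w[ix] - eps)))
      expect_equal(p$grad[ix], (f1 - f2) / (2 * eps), tolerance = 1e-4)
    }
  }
})
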