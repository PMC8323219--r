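test_that("shape contracts hold for test and production geometries", {
  tiny <- backbone_config("tiny")
  expect_equal(feature_map_shape(tiny), c(64, 8, 8))
  prod <- backbone_config("fundus1024")
  expect_equal(feature_map_shape(prod), c(2048, 32, 32))
  expect_error(backbone_config("custom", input_size = 50, channels = c(8, 16)), "stride")
})

test_that("extraction produces the configured maps; zero image gives zero maps", {
  ns <- asNamespace("fundusgcn")
  cfg <- backbone_config("tiny")
  params <- ns$init_backbone(cfg, seed = 5)
  imgs <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  maps <- extract_feature_maps(imgs, cfg, params)
  expect_equal(dim(maps), c(8, 8, 64, 2))
  # biases initialise to zero, so a constant-zero image maps to zero
  zmaps <- extract_feature_maps(array(0, c(64, 64, 3, 1)), cfg, params)
  expect_equal(max(abs(zmaps)), 0)
  expect_error(extract_feature_maps(array(0, c(32, 32, 3, 1)), cfg, params), "expects 64x64")
})

test_that("downsampling halves the spatial side twice", {
  ns <- asNamespace("fundusgcn")
  cfg <- backbone_config("custom", input_size = 64, channels = c(8))
  params <- ns$init_backbone(cfg, seed = 5)
  maps <- array(rnorm(32 * 32 * 8 * 2), c(32, 32, 8, 2))
  out <- downsample(maps, params)
  expect_equal(dim(out), c(8, 8, 8, 2))
  m44 <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  expect_equal(dim(downsample(m44, params))[1:2], c(1, 1))
  expect_error(downsample(array(0, c(2, 2, 8, 1)), params), "too small")
})

test_that("im2col convolution agrees with a direct spatial-convolution oracle", {
  ns <- asNamespace("fundusgcn")
  set.seed(11)
  for (case in 1:5) {
    k <- sample(c(1, 3), 1)
    stride <- sample(1:2, 1)
    pad <- if (k == 3) 1 else 0
    C <- sample(1:3, 1)
    Cout <- sample(1:4, 1)
    H <- sample(5:9, 1)
    x <- array(rnorm(H * H * C * 2), c(H, H, C, 2))
    ly <- ns$new_conv_layer(C, Cout, k = k, stride = stride, pad = pad)
    out <- ns$conv_forward(x, ly)$out
    for (b in 1:2) {
      xi <- array(x[, , , b], dim(x)[1:3])
      expect_equal(
        array(out[, , , b], dim(out)[1:3]),
        oracle_conv2d(xi, ly$W, ly$b, k, stride, pad),
        tolerance = 1e-10
      )
    }
  }
  # delta image through an identity kernel reproduces the shifted response
  x <- array(0, c(6, 6, 1, 1))
  x[3, 4, 1, 1] <- 1
  ly <- ns$new_conv_layer(1, 1, k = 3, stride = 1, pad = 1)
  ly$W <- matrix(0, 9, 1)
  ly$W[5, 1] <- 1 # centre tap
  expect_equal(ns$conv_forward(x, ly)$out, x)
})

test_that("global max pool is an exhaustive per-channel spatial maximum", {
  maps <- array(c(1, 3, 2, 4), c(2, 2, 1, 1))
  expect_equal(global_max_pool(maps), matrix(4))
  neg <- array(-(1:8), c(2, 2, 2, 1))
  expect_equal(global_max_pool(neg), matrix(c(-1, -5), 1))
  set.seed(2)
  r <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  got <- global_max_pool(r)
  for (b in 1:2) {
    for (ch in 1:3) {
      expect_equal(got[b, ch], max(r[, , ch, b]))
    }
  }
  # permutation invariance over spatial positions
  perm <- r[sample(4), sample(5), , , drop = FALSE]
  expect_equal(global_max_pool(perm), got)
})

test_that("backbone gradients agree with finite differences end to end", {
  ns <- asNamespace("fundusgcn")
  set.seed(3)
  cfg <- backbone_config("custom", input_size = 16, channels = c(4, 6))
  params <- ns$init_backbone(cfg, seed = 3)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- matrix(rbinom(2 * 6, 1, 0.5), 2, 6)
  loss_of <- function(p) {
    fw <- ns$backbone_forward_cache(x, p)
    multilabel_softmargin_loss(fw$F, y)
  }
  fw <- ns$backbone_forward_cache(x, params)
  grads <- ns$backbone_backward(ns$loss_grad(fw$F, y), fw, params)
  eps <- 1e-6
  for (spot in list(
    list(grp = "stages", i = 1), list(grp = "stages", i = 2),
    list(grp = "down", i = 1), list(grp = "down", i = 2)
  )) {
    W <- params[[spot$grp]][[spot$i]]$W
    for (j in sample(length(W), 4)) {
      pp <- pm <- params
      pp[[spot$grp]][[spot$i]]$W[j] <- W[j] + eps
      pm[[spot$grp]][[spot$i]]$W[j] <- W[j] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(grads[[spot$grp]][[spot$i]]$dW[j], num, tolerance = 1e-4)
    }
  }
})

test_that("feature path is deterministic and images round-trip from PNG", {
  ns <- asNamespace("fundusgcn")
  cfg <- backbone_config("tiny")
  params <- ns$init_backbone(cfg, seed = 8)
  img <- render_image(c(1, 0, 1, 0), render_spec(64), seed = 4)
  f <- tempfile(fileext = ".png")
  png::writePNG(img, f)
  batch <- load_image_batch(c(f, f), 64)
  expect_equal(dim(batch), c(64, 64, 3, 2))
  expect_equal(batch[, , , 1], batch[, , , 2])
  F1 <- global_max_pool(downsample(extract_feature_maps(batch, cfg, params), params))
  F2 <- global_max_pool(downsample(extract_feature_maps(batch, cfg, params), params))
  expect_identical(F1, F2)
  expect_error(load_image_batch(f, 32), "expected 32x32")
})
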