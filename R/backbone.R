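#' Configure the convolutional image backbone
#'
#' The backbone turns an RGB image into convolutional feature maps, halves the
#' spatial resolution twice with 3x3 stride-2 convolutions, and max-pools the
#' maps into a one-dimensional feature vector F. Each extraction stage is a
#' 3x3 stride-2 convolution (padding 1) followed by ReLU, so an input of size
#' S with `length(channels)` stages yields maps of side `S / 2^stages`; the
#' final channel count is the feature dimension D.
#'
#' Two presets are bundled:
#' * `"tiny"` — 64 x 64 input, channels 16/32/64 (D = 64): the test-scale
#'   backbone trained from scratch in the package's own experiments.
#' * `"fundus1024"` — the production-scale geometry: 1024 x 1024 input, maps
#'   of 2048 x 32 x 32 before downsampling, D = 2048.
#'
#' @param preset `"tiny"`, `"fundus1024"`, or `"custom"`.
#' @param input_size Square input side in pixels (custom preset).
#' @param channels Integer vector of per-stage output channels; the last entry
#'   is the feature dimension D.
#' @return Object of class `backbone_config`.
#' @export
backbone_config <- function(preset = c("tiny", "fundus1024", "custom"),
                            input_size = NULL, channels = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = list(input_size = 64L, channels = c(16L, 32L, 64L)),
    fundus1024 = list(input_size = 1024L, channels = c(64L, 128L, 512L, 1024L, 2048L)),
    custom = {
      if (is.null(input_size) || is.null(channels)) {
        abort("Custom preset requires `input_size` and `channels`.")
      }
      list(input_size = as.integer(input_size), channels = as.integer(channels))
    }
  )
  stride_total <- 2L^length(cfg$channels)
  if (cfg$input_size %% stride_total != 0) {
    abort(sprintf(
      "Input size %d is not a multiple of the backbone's total stride %d.",
      cfg$input_size, stride_total
    ))
  }
  structure(
    list(
      preset = preset, input_size = cfg$input_size, channels = cfg$channels,
      feature_dim = cfg$channels[length(cfg$channels)]
    ),
    class = "backbone_config"
  )
}

#' Feature-map shape implied by a backbone configuration
#'
#' @param cfg A [backbone_config()].
#' @return Integer vector `c(channels, height, width)` of the extraction
#'   stage's output (before downsampling).
#' @export
feature_map_shape <- function(cfg) {
  side <- cfg$input_size %/% 2L^length(cfg$channels)
  c(cfg$feature_dim, side, side)
}

# backbone parameters: extraction convs + the two stride-2 downsampling convs
init_backbone <- function(cfg, seed = 1L) {
  with_seed(seed, {
    in_ch <- 3L
    stages <- lapply(cfg$channels, function(out_ch) {
      ly <- new_conv_layer(in_ch, out_ch, k = 3L, stride = 2L, pad = 1L)
      in_ch <<- out_ch
      ly
    })
    D <- cfg$feature_dim
    down <- list(
      new_conv_layer(D, D, k = 3L, stride = 2L, pad = 1L),
      new_conv_layer(D, D, k = 3L, stride = 2L, pad = 1L)
    )
    list(stages = stages, down = down)
  })
}

#' Extract convolutional feature maps from an image batch
#'
#' @param images (H, W, 3, B) array of RGB values in `[0, 1]`, with H = W =
#'   `cfg$input_size`.
#' @param cfg A [backbone_config()].
#' @param params Backbone parameters (internal; created by the training
#'   functions). Passing trained parameters reproduces the trained features.
#' @return (h, w, C, B) feature-map array.
#' @export
extract_feature_maps <- function(images, cfg, params) {
  d <- dim(images)
  if (length(d) != 4 || d[3] != 3) abort("`images` must be an (H, W, 3, B) array.")
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    abort(sprintf(
      "Images are %dx%d but the backbone expects %dx%d.",
      d[1], d[2], cfg$input_size, cfg$input_size
    ))
  }
  x <- images
  for (ly in params$stages) {
    x <- relu_forward(conv_forward(x, ly)$out)$out
  }
  x
}

#' Downsample feature maps with two stride-2 convolutions
#'
#' Two successive 3x3 stride-2 convolutions (padding 1), each followed by
#' ReLU; the spatial side halves twice (32 -> 16 -> 8 at production scale).
#'
#' @param maps (h, w, C, B) feature-map array with h, w >= 4.
#' @param params Backbone parameters holding the two downsampling layers.
#' @return (h/4, w/4, C, B) array.
#' @export
downsample <- function(maps, params) {
  d <- dim(maps)
  if (d[1] < 4 || d[2] < 4) {
    abort(sprintf("Feature maps %dx%d too small to halve twice (need >= 4).", d[1], d[2]))
  }
  x <- relu_forward(conv_forward(maps, params$down[[1]])$out)$out
  relu_forward(conv_forward(x, params$down[[2]])$out)$out
}

#' Global (adaptive) max pooling
#'
#' Per-channel maximum over all spatial positions, collapsing (h, w, C, B)
#' maps into a B x C feature matrix regardless of the spatial size.
#'
#' @param maps (h, w, C, B) array.
#' @return B x C matrix of image features.
#' @export
global_max_pool <- function(maps) {
  pool_forward(maps)$out
}

# full feature path with caches, used by the training loop
backbone_forward_cache <- function(images, params) {
  caches <- list()
  x <- images
  for (i in seq_along(params$stages)) {
    cf <- conv_forward(x, params$stages[[i]])
    rf <- relu_forward(cf$out)
    caches[[i]] <- list(conv = cf$cache, mask = rf$mask)
    x <- rf$out
  }
  nd <- length(params$down)
  dcaches <- list()
  for (i in seq_len(nd)) {
    cf <- conv_forward(x, params$down[[i]])
    rf <- relu_forward(cf$out)
    dcaches[[i]] <- list(conv = cf$cache, mask = rf$mask)
    x <- rf$out
  }
  pf <- pool_forward(x)
  list(F = pf$out, stage_caches = caches, down_caches = dcaches, pool = pf)
}

backbone_backward <- function(dF, fw, params) {
  dx <- pool_backward(dF, fw$pool)
  nd <- length(params$down)
  gdown <- vector("list", nd)
  for (i in rev(seq_len(nd))) {
    cc <- fw$down_caches[[i]]
    bb <- conv_backward(relu_backward(dx, cc$mask), cc$conv)
    gdown[[i]] <- list(dW = bb$dW, db = bb$db)
    dx <- bb$dx
  }
  ns <- length(params$stages)
  gstages <- vector("list", ns)
  for (i in rev(seq_len(ns))) {
    cc <- fw$stage_caches[[i]]
    bb <- conv_backward(relu_backward(dx, cc$mask), cc$conv)
    gstages[[i]] <- list(dW = bb$dW, db = bb$db)
    dx <- bb$dx
  }
  list(stages = gstages, down = gdown)
}

#' Load a batch of images into an array
#'
#' Reads PNG images, checks the expected square size and RGB channel count,
#' and stacks them into the (H, W, 3, B) layout the backbone consumes. Values
#' are kept in `[0, 1]` (the small-CNN normalization convention).
#'
#' @param paths Character vector of PNG paths.
#' @param input_size Expected square side in pixels.
#' @return (H, W, 3, B) array.
#' @export
load_image_batch <- function(paths, input_size) {
  B <- length(paths)
  out <- array(0, c(input_size, input_size, 3L, B))
  for (i in seq_len(B)) {
    img <- png::readPNG(paths[[i]])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    if (dim(img)[1] != input_size || dim(img)[2] != input_size) {
      abort(sprintf(
        "Image '%s' is %dx%d, expected %dx%d.",
        paths[[i]], dim(img)[1], dim(img)[2], input_size, input_size
      ))
    }
    out[, , , i] <- img
  }
  out
}
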