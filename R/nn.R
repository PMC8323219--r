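# Minimal convolutional-network primitives used by the image backbone and the
# training loop. Tensors are base-R arrays in (H, W, C, B) layout; convolution
# is im2col + BLAS matmul; backward passes are exact (verified against finite
# differences in the test suite).

# im2col index matrix for one padded image: P = Ho*Wo rows (output position,
# row-major within the (Ho, Wo) array layout), K = k*k*C columns (ky fastest,
# then kx, then channel). Entries are linear indices into the padded
# (Hp, Wp, C) array.
conv_index <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  y0 <- (oy - 1L) * stride
  x0 <- (ox - 1L) * stride
  ky <- rep(seq_len(k), times = k * C)
  kx <- rep(rep(seq_len(k), each = k), times = C)
  kc <- rep(seq_len(C), each = k * k)
  # idx[p, q] = (y0_p + ky_q) + (x0_p + kx_q - 1) * Hp + (kc_q - 1) * Hp * Wp
  idx <- outer(y0, ky, "+") + outer(x0, kx - 1L, "+") * Hp +
    matrix((kc - 1L) * Hp * Wp, nrow = Ho * Wo, ncol = k * k * C, byrow = TRUE)
  list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, P = Ho * Wo, K = k * k * C)
}

# index geometry cache (keyed by layer geometry; sizes are fixed within a fit)
.conv_cache <- new.env(parent = emptyenv())

conv_index_cached <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  got <- .conv_cache[[key]]
  if (is.null(got)) {
    got <- conv_index(H, W, C, k, stride, pad)
    .conv_cache[[key]] <- got
  }
  got
}

new_conv_layer <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L) {
  fan_in <- k * k * in_ch
  bound <- 1 / sqrt(fan_in)
  list(
    W = matrix(stats::runif(fan_in * out_ch, -bound, bound), fan_in, out_ch),
    b = numeric(out_ch),
    in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
    stride = as.integer(stride), pad = as.integer(pad)
  )
}

conv_forward <- function(x, layer) {
  d <- dim(x)
  if (d[3] != layer$in_ch) {
    abort(sprintf("Convolution expects %d input channels, got %d.", layer$in_ch, d[3]))
  }
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  g <- conv_index_cached(H, W, C, layer$k, layer$stride, layer$pad)
  xp <- array(0, c(g$Hp, g$Wp, C, B))
  xp[layer$pad + seq_len(H), layer$pad + seq_len(W), , ] <- x
  xpv <- as.vector(xp)
  npad <- g$Hp * g$Wp * C
  cols <- matrix(0, g$P * B, g$K)
  base <- as.vector(g$idx)
  for (b in seq_len(B)) {
    v <- xpv[base + (b - 1L) * npad]
    cols[(b - 1L) * g$P + seq_len(g$P), ] <- v
  }
  out <- cols %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  # rows are grouped by image (position fastest) -> (Ho, Wo, B, Cout) -> permute
  arr <- aperm(array(out, c(g$Ho, g$Wo, B, layer$out_ch)), c(1, 2, 4, 3))
  list(out = arr, cache = list(cols = cols, g = g, B = B, H = H, W = W, C = C, layer = layer))
}

conv_backward <- function(dout, cache) {
  g <- cache$g
  B <- cache$B
  layer <- cache$layer
  dall <- matrix(aperm(dout, c(1, 2, 4, 3)), g$P * B, layer$out_ch)
  dW <- crossprod(cache$cols, dall)
  db <- colSums(dall)
  dcols <- dall %*% t(layer$W)
  npad <- g$Hp * g$Wp * cache$C
  dxp <- numeric(npad * B)
  base <- as.vector(g$idx)
  for (b in seq_len(B)) {
    vals <- as.vector(dcols[(b - 1L) * g$P + seq_len(g$P), ])
    acc <- rowsum(vals, base)
    where <- as.integer(rownames(acc)) + (b - 1L) * npad
    dxp[where] <- dxp[where] + acc[, 1]
  }
  dxp <- array(dxp, c(g$Hp, g$Wp, cache$C, B))
  dx <- dxp[layer$pad + seq_len(cache$H), layer$pad + seq_len(cache$W), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_backward <- function(dout, mask) dout * mask

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# per-channel spatial max over an (H, W, C, B) batch -> B x C feature matrix
pool_forward <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  m <- matrix(x, HW, d[3] * d[4])
  am <- max.col(t(m), ties.method = "first")
  vals <- m[cbind(am, seq_along(am))]
  list(out = t(matrix(vals, d[3], d[4])), argmax = am, dims = d)
}

pool_backward <- function(dF, cache) {
  d <- cache$dims
  HW <- d[1] * d[2]
  dx <- numeric(HW * d[3] * d[4])
  lin <- cache$argmax + (seq_along(cache$argmax) - 1L) * HW
  dx[lin] <- as.vector(t(dF))
  array(dx, d)
}
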