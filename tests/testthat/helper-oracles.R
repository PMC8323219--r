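# Independent brute-force reference implementations. These deliberately use
# naive loops (no shared code with the package internals) so they can serve
# as oracles for the vectorized implementations.

oracle_cooccurrence <- function(Y) {
  N <- ncol(Y)
  M <- matrix(0L, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      for (s in seq_len(nrow(Y))) {
        if (Y[s, i] == 1 && Y[s, j] == 1) M[i, j] <- M[i, j] + 1L
      }
    }
  }
  M
}

oracle_conditional <- function(M) {
  N <- ncol(M)
  P <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) P[i, j] <- M[i, j] / M[j, j]
  P
}

oracle_reweight <- function(Ab, p) {
  N <- ncol(Ab)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(N)) if (j != i && Ab[i, j] == 1) s <- s + 1
    for (j in seq_len(N)) {
      A[i, j] <- if (i == j) 1 - p else if (s > 0 && Ab[i, j] == 1) p / s else 0
    }
  }
  A
}

# dense GCN forward: explicit per-entry triple loops, activation on all but
# the last layer
oracle_gcn_forward <- function(X, A_hat, Ws, slope) {
  H <- X
  for (l in seq_along(Ws)) {
    AH <- matrix(0, nrow(A_hat), ncol(H))
    for (i in seq_len(nrow(A_hat))) {
      for (j in seq_len(ncol(H))) {
        AH[i, j] <- sum(A_hat[i, ] * H[, j])
      }
    }
    pre <- matrix(0, nrow(AH), ncol(Ws[[l]]))
    for (i in seq_len(nrow(AH))) {
      for (j in seq_len(ncol(Ws[[l]]))) {
        pre[i, j] <- sum(AH[i, ] * Ws[[l]][, j])
      }
    }
    H <- if (l < length(Ws)) ifelse(pre > 0, pre, slope * pre) else pre
  }
  H
}

# direct evaluation of the per-element cross-entropy loss, no stabilization
oracle_loss <- function(y_pred, y) {
  B <- nrow(y_pred)
  N <- ncol(y_pred)
  total <- 0
  for (b in seq_len(B)) {
    acc <- 0
    for (i in seq_len(N)) {
      s <- 1 / (1 + exp(-y_pred[b, i]))
      acc <- acc + y[b, i] * log(s) + (1 - y[b, i]) * log(1 - s)
    }
    total <- total + (-acc / N)
  }
  total / B
}

oracle_confusion <- function(y_true, y_hat) {
  N <- ncol(y_true)
  out <- data.frame(tp = integer(N), fp = integer(N), tn = integer(N), fn = integer(N))
  for (j in seq_len(N)) {
    for (s in seq_len(nrow(y_true))) {
      t <- y_true[s, j]
      h <- y_hat[s, j]
      if (t == 1 && h == 1) out$tp[j] <- out$tp[j] + 1L
      if (t == 0 && h == 1) out$fp[j] <- out$fp[j] + 1L
      if (t == 0 && h == 0) out$tn[j] <- out$tn[j] + 1L
      if (t == 1 && h == 0) out$fn[j] <- out$fn[j] + 1L
    }
  }
  out
}

oracle_micro <- function(cc) {
  div0 <- function(a, b) if (b > 0) a / b else 0
  op <- div0(sum(cc$tp), sum(cc$tp) + sum(cc$fp))
  or <- div0(sum(cc$tp), sum(cc$tp) + sum(cc$fn))
  c(OP = op, OR = or, OF1 = if (op + or > 0) 2 * op * or / (op + or) else 0)
}

oracle_macro <- function(cc) {
  div0 <- function(a, b) if (b > 0) a / b else 0
  ps <- mapply(div0, cc$tp, cc$tp + cc$fp)
  rs <- mapply(div0, cc$tp, cc$tp + cc$fn)
  cp <- mean(ps)
  cr <- mean(rs)
  c(CP = cp, CR = cr, CF1 = if (cp + cr > 0) 2 * cp * cr / (cp + cr) else 0)
}

# pairwise Mann-Whitney AUC: every positive-negative pair, ties worth 0.5
oracle_auc <- function(scores, truth) {
  pos <- which(truth == 1)
  neg <- which(truth == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    return(NA_real_)
  }
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (scores[p] > scores[q]) 1 else if (scores[p] == scores[q]) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# direct spatial convolution (stride/pad) of one image, no im2col
oracle_conv2d <- function(x, Wmat, bias, k, stride, pad) {
  H <- dim(x)[1]
  W <- dim(x)[2]
  C <- dim(x)[3]
  Cout <- length(bias)
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout))
  # weight column ordering matches the package layout: ky, kx, channel
  Warr <- array(Wmat, c(k, k, C, Cout))
  for (co in seq_len(Cout)) {
    for (oy in seq_len(Ho)) {
      for (ox in seq_len(Wo)) {
        patch <- xp[(oy - 1) * stride + seq_len(k), (ox - 1) * stride + seq_len(k), , drop = FALSE]
        w <- Warr[, , , co, drop = FALSE]
        out[oy, ox, co] <- sum(as.vector(patch) * as.vector(w)) + bias[co]
      }
    }
  }
  out
}
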