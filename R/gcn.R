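#' Initialise a stack of graph-convolution layers
#'
#' Creates the layer weights for a GCN mapping label embeddings (dimension
#' `dims[1]`, 300 in the production configuration) to per-label classifier
#' vectors (dimension `dims[length(dims)]`, matching the image feature
#' dimension D). Weights are uniform in +/- 1/sqrt(fan-in), seeded.
#'
#' @param dims Integer vector of layer widths, e.g. `c(300, 1024, 2048)`.
#' @param seed Integer seed for the initialisation.
#' @param slope LeakyReLU negative slope (default 0.2).
#' @param final_activation Apply the activation after the last layer? Default
#'   `FALSE`: classifier weights must span negative values.
#' @return Object of class `gcn_stack`.
#' @export
gcn_stack <- function(dims, seed = 1L, slope = 0.2, final_activation = FALSE) {
  stopifnot(length(dims) >= 2, all(dims > 0), slope >= 0)
  W <- with_seed(seed, lapply(seq_len(length(dims) - 1L), function(l) {
    bound <- 1 / sqrt(dims[l])
    matrix(stats::runif(dims[l] * dims[l + 1L], -bound, bound), dims[l], dims[l + 1L])
  }))
  structure(
    list(W = W, dims = as.integer(dims), slope = slope, final_activation = final_activation),
    class = "gcn_stack"
  )
}

#' One graph-convolution layer
#'
#' Computes `sigma(A_hat %*% H %*% W)` — node features averaged over the
#' normalized label graph, linearly transformed, passed through LeakyReLU —
#' or the pre-activation product when `apply_activation = FALSE`.
#'
#' @param H N x d_l node feature matrix.
#' @param A_hat N x N normalized adjacency operator.
#' @param W d_l x d_{l+1} weight matrix.
#' @param slope LeakyReLU negative slope.
#' @param apply_activation Apply the nonlinearity?
#' @return N x d_{l+1} matrix.
#' @export
gcn_layer <- function(H, A_hat, W, slope = 0.2, apply_activation = TRUE) {
  if (nrow(H) != nrow(A_hat) || nrow(A_hat) != ncol(A_hat)) {
    abort(sprintf(
      "Adjacency is %dx%d but node features have %d rows.",
      nrow(A_hat), ncol(A_hat), nrow(H)
    ))
  }
  if (ncol(H) != nrow(W)) {
    abort(sprintf("Weight matrix expects %d input features, got %d.", nrow(W), ncol(H)))
  }
  pre <- A_hat %*% H %*% W
  if (apply_activation) leaky_relu(pre, slope) else pre
}

#' Propagate label embeddings through the GCN
#'
#' Folds [gcn_layer()] over the stack with the label feature matrix as the
#' input layer. The activation is applied after every layer except the last
#' (unless the stack was built with `final_activation = TRUE`). The output
#' `Z` (N x D) holds one linear classifier per label.
#'
#' @param X N x d label feature matrix.
#' @param A_hat Normalized adjacency operator.
#' @param stack A [gcn_stack()].
#' @return N x D classifier matrix `Z`.
#' @export
gcn_forward <- function(X, A_hat, stack) {
  if (ncol(X) != stack$dims[1]) {
    abort(sprintf("Stack expects input dimension %d, got %d.", stack$dims[1], ncol(X)))
  }
  H <- X
  L <- length(stack$W)
  for (l in seq_len(L)) {
    act <- l < L || stack$final_activation
    H <- gcn_layer(H, A_hat, stack$W[[l]], stack$slope, act)
  }
  H
}

# forward pass retaining per-layer inputs and pre-activations for backprop
gcn_forward_cache <- function(X, A_hat, stack) {
  H <- X
  L <- length(stack$W)
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    AH <- A_hat %*% H
    pre <- AH %*% stack$W[[l]]
    act <- l < L || stack$final_activation
    caches[[l]] <- list(AH = AH, pre = pre, act = act)
    H <- if (act) leaky_relu(pre, stack$slope) else pre
  }
  list(Z = H, caches = caches)
}

# backprop through the stack; X is fixed, so only weight gradients are needed
gcn_backward <- function(dZ, A_hat, stack, caches) {
  L <- length(stack$W)
  dW <- vector("list", L)
  d <- dZ
  for (l in rev(seq_len(L))) {
    cc <- caches[[l]]
    dpre <- if (cc$act) d * leaky_relu_grad(cc$pre, stack$slope) else d
    dW[[l]] <- crossprod(cc$AH, dpre)
    if (l > 1) {
      dAH <- dpre %*% t(stack$W[[l]])
      d <- crossprod(A_hat, dAH)
    }
  }
  dW
}

#' Apply label classifiers to image features
#'
#' The raw (pre-sigmoid) prediction scores are the inner products of the
#' image feature vector with each label's classifier: `y = F %*% t(Z)`.
#'
#' @param F Length-D feature vector or B x D feature matrix.
#' @param Z N x D classifier matrix from [gcn_forward()].
#' @return Length-N score vector, or B x N score matrix for a batch.
#' @export
score <- function(F, Z) {
  if (is.null(dim(F))) {
    if (length(F) != ncol(Z)) {
      abort(sprintf("Feature vector has length %d, classifiers expect %d.", length(F), ncol(Z)))
    }
    return(drop(Z %*% F))
  }
  if (ncol(F) != ncol(Z)) {
    abort(sprintf("Features have dimension %d, classifiers expect %d.", ncol(F), ncol(Z)))
  }
  F %*% t(Z)
}
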