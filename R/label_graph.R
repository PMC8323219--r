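#' Label co-occurrence counts
#'
#' For an n x N binary annotation matrix, returns the N x N integer matrix
#' `M = t(Y) %*% Y`: off-diagonal `M[i, j]` counts samples carrying both
#' labels, the diagonal holds each label's marginal count.
#'
#' @param Y n x N binary matrix (rows = images, columns = labels). A data
#'   frame of 0/1 columns is accepted.
#' @return N x N symmetric integer matrix, label names preserved.
#' @export
cooccurrence_counts <- function(Y) {
  Y <- check_binary_matrix(Y)
  if (nrow(Y) < 1) abort("Need at least one sample.")
  M <- crossprod(Y)
  storage.mode(M) <- "integer"
  M
}

#' Conditional label probabilities P(L_i | L_j)
#'
#' `P[i, j] = M[i, j] / M[j, j]`: the probability that label i appears given
#' that label j appears, estimated from co-occurrence counts. Asymmetric in
#' general; the diagonal is 1 wherever a label occurs.
#'
#' @param M Co-occurrence count matrix from [cooccurrence_counts()].
#' @return N x N matrix of conditional probabilities.
#' @export
conditional_probabilities <- function(M) {
  marg <- diag(M)
  if (any(marg <= 0)) {
    nm <- colnames(M) %||% as.character(seq_len(ncol(M)))
    abort(sprintf(
      "Label(s) with zero occurrences (conditional probability undefined): %s",
      paste(nm[marg <= 0], collapse = ", ")
    ))
  }
  sweep(M, 2, marg, "/")
}

#' Binarize a conditional-probability matrix
#'
#' Thresholds every entry (diagonal included; the next stage overwrites it):
#' `A'[i, j] = 1` iff `P[i, j] >= tau`. The comparison is `>=`, so an entry
#' exactly at the threshold becomes an edge.
#'
#' @param P Conditional-probability matrix.
#' @param tau Threshold in (0, 1); default 0.3.
#' @return Binary N x N matrix.
#' @export
binarize <- function(P, tau = 0.3) {
  stopifnot(tau > 0, tau < 1)
  A <- (P >= tau) + 0
  dimnames(A) <- dimnames(P)
  A
}

#' Re-weight a binarized adjacency matrix
#'
#' Balances a label's own feature against its neighbours': each off-diagonal
#' edge in row i gets weight `p / s_i` (with `s_i` the row's edge count) and
#' the diagonal gets `1 - p`, so every row with at least one edge sums to 1.
#' Non-edges stay zero, preserving the sparsity the binarization created; a
#' row with no edges keeps an all-zero off-diagonal (row sum `1 - p`).
#'
#' @param A_bin Binary adjacency from [binarize()].
#' @param p Neighbour weight coefficient in (0, 1); default 0.25.
#' @return Re-weighted N x N matrix.
#' @export
reweight <- function(A_bin, p = 0.25) {
  stopifnot(p > 0, p < 1)
  A <- A_bin
  diag(A) <- 0
  s <- rowSums(A)
  scale <- ifelse(s > 0, p / s, 0)
  A <- A * scale
  diag(A) <- 1 - p
  A
}

#' Symmetrically normalize an adjacency matrix
#'
#' Kipf-style propagation operator `D^{-1/2} A D^{-1/2}` with
#' `D = diag(rowSums(A))`. No identity is added: the re-weighting stage has
#' already populated the diagonal. Asymmetry of A is preserved.
#'
#' @param A Non-negative matrix with strictly positive row sums.
#' @return Normalized operator of the same shape.
#' @export
normalize_adjacency <- function(A) {
  if (any(A < 0)) abort("Adjacency must be non-negative.")
  d <- rowSums(A)
  if (any(d <= 0)) abort("Every row sum must be strictly positive before normalization.")
  dm <- 1 / sqrt(d)
  A * outer(dm, dm)
}

#' Build the full label-dependency graph
#'
#' Runs the whole pipeline on a binary annotation matrix (use the *training*
#' split only, so no test-set co-occurrence leaks into the graph): counts ->
#' conditional probabilities -> thresholding at `tau` -> re-weighting by `p`
#' -> symmetric normalization.
#'
#' @inheritParams cooccurrence_counts
#' @inheritParams binarize
#' @inheritParams reweight
#' @return Object of class `label_graph`: a list with elements `counts`, `P`,
#'   `A_bin`, `A`, `A_hat`, `tau`, `p`, `labels`.
#' @export
label_graph <- function(Y, tau = 0.3, p = 0.25) {
  Y <- check_binary_matrix(Y)
  M <- cooccurrence_counts(Y)
  P <- conditional_probabilities(M)
  A_bin <- binarize(P, tau)
  A <- reweight(A_bin, p)
  A_hat <- normalize_adjacency(A)
  structure(
    list(
      counts = M, P = P, A_bin = A_bin, A = A, A_hat = A_hat,
      tau = tau, p = p,
      labels = colnames(Y) %||% as.character(seq_len(ncol(Y)))
    ),
    class = "label_graph"
  )
}

#' @export
print.label_graph <- function(x, ...) {
  n_edges <- sum(x$A_bin) - sum(diag(x$A_bin) > 0)
  cat(sprintf(
    "<label_graph> %d labels, %d directed edges (tau = %g, p = %g)\n",
    length(x$labels), n_edges, x$tau, x$p
  ))
  invisible(x)
}

#' Heatmap of a label graph stage
#'
#' @param object A `label_graph`.
#' @param stage One of "P", "A_bin", "A", "A_hat".
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot label_graph
#' @export
autoplot.label_graph <- function(object, stage = c("P", "A_bin", "A", "A_hat"), ...) {
  stage <- match.arg(stage)
  M <- object[[stage]]
  df <- tibble(
    from = rep(object$labels, times = ncol(M)),
    to = rep(object$labels, each = nrow(M)),
    weight = as.vector(M)
  )
  df$from <- factor(df$from, levels = rev(object$labels))
  df$to <- factor(df$to, levels = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(M))) +
    ggplot2::labs(
      x = "conditioning label (j)", y = "label (i)", fill = stage,
      title = sprintf("Label graph stage %s", stage)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write / read a labelled matrix as TSV
#'
#' Plain-text serialization for graph stages: a header row of label names,
#' then one numeric row per label (row names in the first column). Full
#' double precision is preserved.
#'
#' @param M Numeric matrix with row/column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- as.data.frame(M)
  df <- cbind(label = rownames(M) %||% as.character(seq_len(nrow(M))), df)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}
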