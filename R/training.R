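#' Multi-label soft-margin loss
#'
#' One-versus-all binary cross-entropy on the logistic confidences, averaged
#' over labels and then over the batch:
#' `-(1/N) * sum_i [ y_i log sigma(s_i) + (1 - y_i) log(1 - sigma(s_i)) ]`.
#' Evaluated in the numerically stable logits form
#' `max(s, 0) - s*y + log(1 + exp(-|s|))`, so large scores never overflow.
#'
#' @param y_pred B x N matrix (or length-N vector) of raw scores.
#' @param y Binary targets of the same shape.
#' @return Scalar loss (non-negative; `log(2)` at all-zero scores).
#' @export
multilabel_softmargin_loss <- function(y_pred, y) {
  if (is.null(dim(y_pred))) y_pred <- matrix(y_pred, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  y <- check_binary_matrix(y, "y")
  if (!all(dim(y_pred) == dim(y))) abort("`y_pred` and `y` shapes differ.")
  elt <- pmax(y_pred, 0) - y_pred * y + log1p(exp(-abs(y_pred)))
  mean(rowMeans(elt))
}

# gradient of the loss w.r.t. the raw scores
loss_grad <- function(y_pred, y) {
  (sigmoid(y_pred) - y) / length(y_pred)
}

#' Threshold scores into hard label predictions
#'
#' A label is assigned when its logistic confidence strictly exceeds the
#' threshold; at the default 0.5 this is exactly `score > 0`, so a raw score
#' of 0 is negative.
#'
#' @param y_pred Raw scores (vector or matrix).
#' @param threshold Confidence threshold in (0, 1); default 0.5.
#' @return Binary labels of the same shape.
#' @export
predict_labels <- function(y_pred, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (y_pred > stats::qlogis(threshold)) + 0
}

#' Split a manifest into train / validation / test
#'
#' Seeded shuffle followed by a contiguous cut at the given fractions
#' (70/15/15 by default). The partition is exact up to rounding (sizes differ
#' from `fractions * n` by at most 1) and disjoint. With `by_patient = TRUE`
#' whole patients are assigned to one split, preventing leakage between a
#' patient's two eyes.
#'
#' @param manifest Data frame of samples (one row per image).
#' @param fractions Length-3 numeric summing to 1: train, validation, test.
#' @param seed Integer seed for the shuffle.
#' @param by_patient Split at the patient level using the `patient_id` column.
#' @return The manifest as a tibble with an added `split` factor column
#'   (`"train"`, `"validation"`, `"test"`), original row order preserved.
#' @export
split_dataset <- function(manifest, fractions = c(0.70, 0.15, 0.15), seed = 1L,
                          by_patient = FALSE) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (length(fractions) != 3) abort("`fractions` must have 3 entries (train/validation/test).")
  n <- nrow(manifest)
  if (n < 3) abort("Need at least 3 samples to split.")
  assign_units <- function(units) {
    m <- length(units)
    ord <- with_seed(derive_seed(seed, "split"), sample.int(m))
    n1 <- round(fractions[1] * m)
    n2 <- round(fractions[2] * m)
    sp <- rep("test", m)
    sp[ord <= n1] <- "train"
    sp[ord > n1 & ord <= n1 + n2] <- "validation"
    stats::setNames(sp, units)
  }
  if (by_patient) {
    if (!"patient_id" %in% names(manifest)) {
      abort("`by_patient = TRUE` requires a `patient_id` column.")
    }
    pat <- as.character(manifest$patient_id)
    sp <- assign_units(unique(pat))[pat]
  } else {
    sp <- assign_units(as.character(seq_len(n)))
  }
  out <- as_tibble(manifest)
  out$split <- factor(unname(sp), levels = c("train", "validation", "test"))
  out
}

#' Optimizer settings for end-to-end training
#'
#' SGD with momentum 0.9 and weight decay 1e-4; the image backbone trains at
#' learning rate 0.01 and the GCN head (everything else) at 0.1.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size B.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param lr_backbone Learning rate for the backbone parameter group.
#' @param lr_head Learning rate for the GCN head parameter group.
#' @return Object of class `optim_config`.
#' @export
optim_config <- function(epochs = 30L, batch_size = 8L, momentum = 0.9,
                         weight_decay = 1e-4, lr_backbone = 0.01, lr_head = 0.1) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_backbone > 0, lr_head > 0)
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      momentum = momentum, weight_decay = weight_decay,
      lr_backbone = lr_backbone, lr_head = lr_head
    ),
    class = "optim_config"
  )
}

# assemble an untrained model: backbone params + GCN stack + fixed X, A_hat
new_model <- function(X, A_hat, backbone_cfg, gcn_dims = NULL, seed = 1L,
                      slope = 0.2) {
  D <- backbone_cfg$feature_dim
  if (is.null(gcn_dims)) gcn_dims <- c(ncol(X), 2L * ncol(X), D)
  if (gcn_dims[1] != ncol(X)) abort("First GCN dimension must equal the embedding dimension.")
  if (gcn_dims[length(gcn_dims)] != D) {
    abort("Last GCN dimension must equal the backbone feature dimension D.")
  }
  structure(
    list(
      X = X, A_hat = A_hat, backbone_cfg = backbone_cfg,
      backbone = init_backbone(backbone_cfg, derive_seed(seed, "backbone")),
      stack = gcn_stack(gcn_dims, derive_seed(seed, "gcn"), slope = slope),
      labels = rownames(X) %||% as.character(seq_len(nrow(X)))
    ),
    class = "fgcn_model"
  )
}

#' @export
print.fgcn_model <- function(x, ...) {
  cat(sprintf(
    "<fgcn_model> %d labels | backbone '%s' (D = %d) | GCN dims %s\n",
    length(x$labels), x$backbone_cfg$preset, x$backbone_cfg$feature_dim,
    paste(x$stack$dims, collapse = " -> ")
  ))
  invisible(x)
}

model_forward <- function(model, images) {
  bw <- backbone_forward_cache(images, model$backbone)
  gw <- gcn_forward_cache(model$X, model$A_hat, model$stack)
  scores <- bw$F %*% t(gw$Z)
  colnames(scores) <- model$labels
  list(scores = scores, bw = bw, gw = gw)
}

model_backward <- function(model, fw, dscores) {
  dF <- dscores %*% fw$gw$Z
  dZ <- crossprod(dscores, fw$bw$F)
  gb <- backbone_backward(dF, fw$bw, model$backbone)
  gh <- gcn_backward(dZ, model$A_hat, model$stack, fw$gw$caches)
  list(backbone = gb, head = gh)
}

# SGD-with-momentum update on one tensor; PyTorch-style buffers
sgd_step <- function(param, grad, buf, lr, momentum, wd) {
  g <- grad + wd * param
  buf <- momentum * buf + g
  list(param = param - lr * buf, buf = buf)
}

zero_like_model <- function(model) {
  list(
    backbone = list(
      stages = lapply(model$backbone$stages, function(l) list(W = l$W * 0, b = l$b * 0)),
      down = lapply(model$backbone$down, function(l) list(W = l$W * 0, b = l$b * 0))
    ),
    head = lapply(model$stack$W, function(W) W * 0)
  )
}

apply_updates <- function(model, grads, state, optim) {
  mu <- optim$momentum
  wd <- optim$weight_decay
  for (grp in c("stages", "down")) {
    for (i in seq_along(model$backbone[[grp]])) {
      up <- sgd_step(
        model$backbone[[grp]][[i]]$W, grads$backbone[[grp]][[i]]$dW,
        state$backbone[[grp]][[i]]$W, optim$lr_backbone, mu, wd
      )
      model$backbone[[grp]][[i]]$W <- up$param
      state$backbone[[grp]][[i]]$W <- up$buf
      up <- sgd_step(
        model$backbone[[grp]][[i]]$b, grads$backbone[[grp]][[i]]$db,
        state$backbone[[grp]][[i]]$b, optim$lr_backbone, mu, wd
      )
      model$backbone[[grp]][[i]]$b <- up$param
      state$backbone[[grp]][[i]]$b <- up$buf
    }
  }
  for (l in seq_along(model$stack$W)) {
    up <- sgd_step(
      model$stack$W[[l]], grads$head[[l]], state$head[[l]],
      optim$lr_head, mu, wd
    )
    model$stack$W[[l]] <- up$param
    state$head[[l]] <- up$buf
  }
  list(model = model, state = state)
}

manifest_labels <- function(manifest, labels) {
  miss <- setdiff(labels, names(manifest))
  if (length(miss) > 0) {
    abort(sprintf("Manifest lacks label column(s): %s", paste(miss, collapse = ", ")))
  }
  as.matrix(manifest[, labels, drop = FALSE])
}

resolve_paths <- function(manifest, root = NULL) {
  p <- manifest$image_path
  if (!is.null(root)) p <- file.path(root, p)
  p
}

#' Train the fundus multi-label classifier end-to-end
#'
#' Fits the CNN backbone and GCN head jointly with SGD (momentum 0.9, weight
#' decay 1e-4, backbone learning rate 0.01, head learning rate 0.1 by
#' default). The label graph must be built from the training split only.
#' Per-epoch training loss and validation OF1/CF1 are logged, and the model
#' with the best validation CF1 is retained as the checkpoint.
#'
#' @param train,val Manifest tibbles with `image_path` and one binary column
#'   per label.
#' @param graph A [label_graph()] (or bare normalized adjacency matrix).
#' @param X N x d label feature matrix, rows in the manifest's label order.
#' @param backbone_cfg A [backbone_config()].
#' @param gcn_dims GCN layer widths, first = `ncol(X)`, last = feature dim D.
#' @param optim An [optim_config()].
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @param image_root Directory that `image_path` entries are relative to.
#' @param verbose Print one line per epoch.
#' @return Object of class `fgcn_fit`: `model` (best checkpoint),
#'   `final_model`, `log` (per-epoch tibble), `best_epoch`, `labels`.
#' @export
fit_mlgcn <- function(train, val, graph, X, backbone_cfg,
                      gcn_dims = NULL, optim = optim_config(), seed = 1L,
                      image_root = NULL, verbose = FALSE) {
  if (nrow(train) == 0 || nrow(val) == 0) abort("Empty training or validation split.")
  A_hat <- if (inherits(graph, "label_graph")) graph$A_hat else graph
  labels <- rownames(X) %||% colnames(A_hat)
  if (is.null(labels)) abort("Label names must be attached to X (rownames) or the graph.")

  model <- new_model(X, A_hat, backbone_cfg, gcn_dims, seed = seed)
  state <- zero_like_model(model)

  sz <- backbone_cfg$input_size
  x_train <- load_image_batch(resolve_paths(train, image_root), sz)
  y_train <- manifest_labels(train, labels)
  x_val <- load_image_batch(resolve_paths(val, image_root), sz)
  y_val <- manifest_labels(val, labels)

  n <- nrow(train)
  B <- optim$batch_size
  log <- vector("list", optim$epochs)
  best <- list(cf1 = -Inf, epoch = NA_integer_, model = model)

  for (epoch in seq_len(optim$epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("epoch", epoch)), sample.int(n))
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = B)) {
      take <- ord[start:min(start + B - 1L, n)]
      xb <- x_train[, , , take, drop = FALSE]
      yb <- y_train[take, , drop = FALSE]
      fw <- model_forward(model, xb)
      epoch_loss <- epoch_loss + multilabel_softmargin_loss(fw$scores, yb)
      n_batches <- n_batches + 1L
      grads <- model_backward(model, fw, loss_grad(fw$scores, yb))
      up <- apply_updates(model, grads, state, optim)
      model <- up$model
      state <- up$state
    }
    val_scores <- predict_scores(model, x_val)
    rep <- metric_report(y_val, val_scores)
    log[[epoch]] <- tibble(
      epoch = epoch,
      train_loss = epoch_loss / n_batches,
      val_OF1 = rep$summary$OF1,
      val_CF1 = rep$summary$CF1
    )
    if (rep$summary$CF1 > best$cf1) {
      best <- list(cf1 = rep$summary$CF1, epoch = epoch, model = model)
    }
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  val OF1 %.3f  CF1 %.3f",
        epoch, epoch_loss / n_batches, rep$summary$OF1, rep$summary$CF1
      ))
    }
  }
  structure(
    list(
      model = best$model, final_model = model, log = dplyr::bind_rows(log),
      best_epoch = best$epoch, labels = labels, optim = optim, seed = seed
    ),
    class = "fgcn_fit"
  )
}

# raw scores for an in-memory image array (batched to bound memory)
predict_scores <- function(model, images, batch = 32L) {
  B <- dim(images)[4]
  Z <- gcn_forward(model$X, model$A_hat, model$stack)
  out <- matrix(0, B, nrow(Z))
  for (start in seq(1L, B, by = batch)) {
    take <- start:min(start + batch - 1L, B)
    fw <- backbone_forward_cache(images[, , , take, drop = FALSE], model$backbone)
    out[take, ] <- fw$F %*% t(Z)
  }
  colnames(out) <- model$labels
  out
}

#' Predict lesion scores for a manifest
#'
#' @param object A fitted `fgcn_fit`.
#' @param manifest Manifest tibble with `image_path`.
#' @param image_root Directory that paths are relative to.
#' @param type `"score"` (raw), `"prob"` (sigmoid confidences) or `"label"`
#'   (hard 0/1 at confidence 0.5).
#' @param ... Unused.
#' @return Tibble with `image_path` and one column per label.
#' @export
predict.fgcn_fit <- function(object, manifest, image_root = NULL,
                             type = c("score", "prob", "label"), ...) {
  type <- match.arg(type)
  images <- load_image_batch(
    resolve_paths(manifest, image_root),
    object$model$backbone_cfg$input_size
  )
  s <- predict_scores(object$model, images)
  out <- switch(type,
    score = s,
    prob = sigmoid(s),
    label = predict_labels(s)
  )
  dplyr::bind_cols(tibble(image_path = manifest$image_path), as_tibble(out))
}

#' Evaluate a fitted model on a manifest
#'
#' @param fit A `fgcn_fit` (its best-validation checkpoint is used).
#' @param manifest Manifest with `image_path` and label columns.
#' @param image_root Directory that paths are relative to.
#' @return A [metric_report()].
#' @export
evaluate_model <- function(fit, manifest, image_root = NULL) {
  model <- if (inherits(fit, "fgcn_fit")) fit$model else fit
  images <- load_image_batch(
    resolve_paths(manifest, image_root), model$backbone_cfg$input_size
  )
  y <- manifest_labels(manifest, model$labels)
  metric_report(y, predict_scores(model, images))
}

#' @export
print.fgcn_fit <- function(x, ...) {
  cat(sprintf(
    "<fgcn_fit> %d epochs, best validation CF1 %.3f at epoch %d\n",
    nrow(x$log), max(x$log$val_CF1), x$best_epoch
  ))
  invisible(x)
}

#' @method tidy fgcn_fit
#' @export
tidy.fgcn_fit <- function(x, ...) x$log

#' @method glance fgcn_fit
#' @export
glance.fgcn_fit <- function(x, ...) {
  tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_CF1 = max(x$log$val_CF1),
    final_train_loss = x$log$train_loss[nrow(x$log)]
  )
}

#' Training curves for a fitted model
#'
#' @param object A `fgcn_fit`.
#' @param ... Unused.
#' @return A ggplot object with loss and validation F1 per epoch.
#' @method autoplot fgcn_fit
#' @export
autoplot.fgcn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training trajectory") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
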