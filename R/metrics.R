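#' Per-class confusion counts
#'
#' Tallies TP/FP/TN/FN separately for each of the N labels over an n-image
#' evaluation set.
#'
#' @param y_true n x N binary ground-truth matrix.
#' @param y_hat n x N binary prediction matrix.
#' @return A tibble with one row per label: `label`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_hat) {
  y_true <- check_binary_matrix(y_true, "y_true")
  y_hat <- check_binary_matrix(y_hat, "y_hat")
  if (!all(dim(y_true) == dim(y_hat))) {
    abort(sprintf(
      "Shape mismatch: y_true is %dx%d, y_hat is %dx%d.",
      nrow(y_true), ncol(y_true), nrow(y_hat), ncol(y_hat)
    ))
  }
  tibble(
    label = colnames(y_true) %||% as.character(seq_len(ncol(y_true))),
    tp = as.integer(colSums(y_true == 1 & y_hat == 1)),
    fp = as.integer(colSums(y_true == 0 & y_hat == 1)),
    tn = as.integer(colSums(y_true == 0 & y_hat == 0)),
    fn = as.integer(colSums(y_true == 1 & y_hat == 0))
  )
}

# precision/recall with the 0/0 -> 0 convention for empty denominators
safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

f1_of <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

#' Micro-averaged (overall) precision, recall and F1
#'
#' Counts are pooled over all classes before forming precision and recall;
#' OF1 is their harmonic mean. Empty denominators yield 0 by convention.
#'
#' @param counts Confusion tibble from [confusion_counts()].
#' @return A one-row tibble: `OP`, `OR`, `OF1`.
#' @export
micro_scores <- function(counts) {
  OP <- safe_div(sum(counts$tp), sum(counts$tp) + sum(counts$fp))
  OR <- safe_div(sum(counts$tp), sum(counts$tp) + sum(counts$fn))
  tibble(OP = OP, OR = OR, OF1 = f1_of(OP, OR))
}

#' Macro-averaged (per-class) precision, recall and F1
#'
#' Precision and recall are computed per class, averaged over the N classes,
#' and combined by the harmonic mean into CF1.
#'
#' @inheritParams micro_scores
#' @return A one-row tibble: `CP`, `CR`, `CF1`.
#' @export
macro_scores <- function(counts) {
  CP <- mean(safe_div(counts$tp, counts$tp + counts$fp))
  CR <- mean(safe_div(counts$tp, counts$tp + counts$fn))
  tibble(CP = CP, CR = CR, CF1 = f1_of(CP, CR))
}

#' Per-class accuracy
#'
#' `(TP + TN) / (TP + FN + TN + FP)` for each label.
#'
#' @inheritParams micro_scores
#' @return A tibble with `label` and `accuracy`.
#' @export
per_class_accuracy <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (any(n <= 0)) abort("Accuracy undefined for an empty evaluation set.")
  tibble(label = counts$label, accuracy = (counts$tp + counts$tn) / n)
}

#' Per-class AUC (rank / Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive image receives a higher
#' score than a randomly chosen negative one, with tied pairs counted 0.5
#' (midrank formulation). A class with no positive or no negative image has
#' no defined AUC: it is reported as `NA` with a warning and should be
#' excluded from summaries.
#'
#' @param scores n x N matrix of real-valued scores (any monotone scale).
#' @param y_true n x N binary ground truth.
#' @return A tibble with `label` and `auc` (`NA` for degenerate classes).
#' @export
per_class_auc <- function(scores, y_true) {
  y_true <- check_binary_matrix(y_true, "y_true")
  if (!all(dim(scores) == dim(y_true))) abort("`scores` and `y_true` shapes differ.")
  labels <- colnames(y_true) %||% as.character(seq_len(ncol(y_true)))
  auc <- vapply(seq_len(ncol(y_true)), function(j) {
    pos <- y_true[, j] == 1
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) {
      return(NA_real_)
    }
    r <- rank(scores[, j]) # midranks: ties contribute 0.5 per pair
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
  if (anyNA(auc)) {
    warn(sprintf(
      "AUC undefined (all-positive or all-negative class): %s",
      paste(labels[is.na(auc)], collapse = ", ")
    ))
  }
  tibble(label = labels, auc = auc)
}

#' Full multi-label evaluation report
#'
#' Thresholds the scores at a confidence of 0.5 (strictly greater, i.e. raw
#' score > 0), tallies confusion counts and assembles the complete metric
#' suite: micro OP/OR/OF1, macro CP/CR/CF1, and per-class accuracy and AUC.
#'
#' @param y_true n x N binary ground truth.
#' @param scores n x N raw (pre-sigmoid) scores.
#' @param threshold Confidence threshold for the hard predictions.
#' @return Object of class `metric_report`: list with `summary` (one-row
#'   tibble) and `per_class` (N-row tibble).
#' @export
metric_report <- function(y_true, scores, threshold = 0.5) {
  y_hat <- predict_labels(scores, threshold)
  counts <- confusion_counts(y_true, y_hat)
  summary <- dplyr::bind_cols(micro_scores(counts), macro_scores(counts))
  per_class <- dplyr::left_join(
    per_class_accuracy(counts),
    per_class_auc(scores, y_true),
    by = "label"
  )
  structure(
    list(summary = summary, per_class = per_class, counts = counts, threshold = threshold),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$summary
  cat("Multi-label evaluation report\n")
  cat(sprintf(
    "  micro: OP = %.3f  OR = %.3f  OF1 = %.3f\n", s$OP, s$OR, s$OF1
  ))
  cat(sprintf(
    "  macro: CP = %.3f  CR = %.3f  CF1 = %.3f\n", s$CP, s$CR, s$CF1
  ))
  cat("  per lesion:\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf(
      "    %-26s Acc = %.3f  AUC = %s\n", pc$label[i], pc$accuracy[i],
      ifelse(is.na(pc$auc[i]), "  NA", sprintf("%.3f", pc$auc[i]))
    ))
  }
  invisible(x)
}

#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) x$summary

#' Bar chart of per-class accuracy and AUC
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, c("accuracy", "auc"),
    names_to = "metric", values_to = "value"
  )
  df$label <- factor(df$label, levels = object$per_class$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-lesion accuracy and AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Serialize a metric report to JSON
#'
#' @param x A `metric_report`.
#' @param path Output path.
#' @export
write_metric_report <- function(x, path) {
  obj <- list(
    summary = as.list(x$summary),
    per_class = x$per_class,
    threshold = x$threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
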