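# 3-image, 2-label toy: class 1 TP=1 FN=1 FP=0 TN=1; class 2 TP=2 FN=0 FP=0 TN=1
toy_true <- rbind(c(1, 0), c(1, 1), c(0, 1))
toy_hat <- rbind(c(1, 0), c(0, 1), c(0, 1))

test_that("confusion counts match hand enumeration", {
  cc <- confusion_counts(toy_true, toy_hat)
  expect_equal(cc$tp, c(1, 2))
  expect_equal(cc$fn, c(1, 0))
  expect_equal(cc$fp, c(0, 0))
  expect_equal(cc$tn, c(1, 1))
  # counts always partition n per class
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, c(3, 3))

  perfect <- confusion_counts(toy_true, toy_true)
  expect_equal(perfect$fp, c(0, 0))
  expect_equal(perfect$fn, c(0, 0))
  inverted <- confusion_counts(toy_true, 1 - toy_true)
  expect_equal(inverted$tp, c(0, 0))
  expect_equal(inverted$tn, c(0, 0))
  expect_error(confusion_counts(toy_true, toy_hat[1:2, ]), "mismatch")
})

test_that("micro and macro suites reproduce the derived toy values", {
  cc <- confusion_counts(toy_true, toy_hat)
  mi <- micro_scores(cc)
  expect_equal(mi$OP, 1)
  expect_equal(mi$OR, 0.75)
  expect_equal(mi$OF1, 6 / 7)
  ma <- macro_scores(cc)
  expect_equal(ma$CP, 1)
  expect_equal(ma$CR, 0.75)
  expect_equal(ma$CF1, 6 / 7)
  acc <- per_class_accuracy(cc)
  expect_equal(acc$accuracy, c(2 / 3, 1))

  perfect <- micro_scores(confusion_counts(toy_true, toy_true))
  expect_equal(unlist(perfect), c(OP = 1, OR = 1, OF1 = 1))
  # no positives anywhere: all scores 0 by the 0/0 -> 0 convention
  none <- confusion_counts(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(micro_scores(none)$OF1, 0)
  expect_equal(macro_scores(none)$CF1, 0)
  expect_equal(per_class_accuracy(none)$accuracy, c(1, 1))
})

test_that("single-class macro collapses to micro", {
  y <- matrix(rbinom(20, 1, 0.5), 20, 1)
  h <- matrix(rbinom(20, 1, 0.5), 20, 1)
  cc <- confusion_counts(y, h)
  expect_equal(macro_scores(cc)$CF1, micro_scores(cc)$OF1)
})

test_that("AUC is the pairwise positive-over-negative probability", {
  s <- matrix(c(0.1, 0.4, 0.35, 0.8), 4, 1)
  y <- matrix(c(0, 0, 1, 1), 4, 1)
  expect_equal(per_class_auc(s, y)$auc, 0.75)
  # perfect separation and all-ties
  expect_equal(per_class_auc(matrix(c(1, 2, 3, 4)), matrix(c(0, 0, 1, 1)))$auc, 1)
  expect_equal(per_class_auc(matrix(rep(1, 4)), matrix(c(0, 1, 0, 1)))$auc, 0.5)
  # invariant under strictly increasing transforms
  expect_equal(per_class_auc(exp(s), y)$auc, 0.75)
  # degenerate class is NA with a warning, never 0 or 1
  ydeg <- cbind(c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_warning(a <- per_class_auc(cbind(s, s), ydeg), "undefined")
  expect_true(is.na(a$auc[1]))
  expect_equal(a$auc[2], 0.75)
})

test_that("metric suite matches brute-force oracles on 200 random instances", {
  skip_if_not_installed("pROC")
  for (case in 1:200) {
    set.seed(9000 + case)
    n <- sample(3:30, 1)
    N <- sample(1:6, 1)
    y <- matrix(rbinom(n * N, 1, runif(1, 0.2, 0.8)), n, N)
    h <- matrix(rbinom(n * N, 1, 0.5), n, N)
    s <- matrix(rnorm(n * N), n, N)
    # score ties are common in practice; inject some
    s[sample(length(s), ceiling(length(s) / 4))] <- 0
    cc <- confusion_counts(y, h)
    occ <- oracle_confusion(y, h)
    expect_identical(cbind(cc$tp, cc$fp, cc$tn, cc$fn), cbind(occ$tp, occ$fp, occ$tn, occ$fn))
    expect_equal(unlist(micro_scores(cc)), oracle_micro(occ), tolerance = 1e-12)
    expect_equal(unlist(macro_scores(cc)), oracle_macro(occ), tolerance = 1e-12)
    expect_equal(
      per_class_accuracy(cc)$accuracy,
      (occ$tp + occ$tn) / n,
      tolerance = 1e-12
    )
    got_auc <- suppressWarnings(per_class_auc(s, y)$auc)
    for (j in seq_len(N)) {
      expect_equal(got_auc[j], oracle_auc(s[, j], y[, j]), tolerance = 1e-12)
    }
    # swapping prediction and truth transposes FP and FN, accuracy unchanged
    sw <- confusion_counts(h, y)
    expect_equal(sw$fp, cc$fn)
    expect_equal(sw$fn, cc$fp)
    expect_equal(per_class_accuracy(sw)$accuracy, per_class_accuracy(cc)$accuracy)
  }
  # independent library cross-check on one non-degenerate instance
  set.seed(99)
  sc <- rnorm(40)
  yy <- rbinom(40, 1, 0.5)
  expect_equal(
    per_class_auc(matrix(sc), matrix(yy))$auc,
    as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE, direction = "<")))
  )
})

test_that("metric_report assembles the full suite with accessors and JSON", {
  set.seed(10)
  y <- matrix(rbinom(60, 1, 0.5), 20, 3)
  colnames(y) <- c("a", "b", "c")
  s <- matrix(rnorm(60), 20, 3)
  rep <- metric_report(y, s)
  expect_s3_class(rep, "metric_report")
  expect_named(rep$summary, c("OP", "OR", "OF1", "CP", "CR", "CF1"))
  expect_equal(rep$per_class$label, c("a", "b", "c"))
  expect_true(all(unlist(rep$summary) >= 0 & unlist(rep$summary) <= 1))
  expect_identical(tidy(rep), rep$per_class)
  expect_identical(glance(rep), rep$summary)
  expect_s3_class(autoplot(rep), "ggplot")
  f <- tempfile(fileext = ".json")
  write_metric_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$summary$OF1, rep$summary$OF1, tolerance = 1e-12)
  expect_output(print(rep), "OF1")
})
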