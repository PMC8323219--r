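test_that("loss matches its closed forms and a direct unvectorized evaluation", {
  # zero scores: both branches contribute log 0.5 regardless of y
  y <- matrix(c(1, 0, 1, 1), 1, 4)
  expect_equal(multilabel_softmargin_loss(matrix(0, 1, 4), y), log(2), tolerance = 1e-12)
  # sigma(ln 3) = 3/4 so a positive label costs ln(4/3)
  expect_equal(multilabel_softmargin_loss(log(3), 1), log(4 / 3), tolerance = 1e-9)
  # vectorized implementation vs naive direct evaluation
  for (case in 1:20) {
    set.seed(8000 + case)
    y_pred <- matrix(rnorm(5 * 8, sd = 3), 5, 8)
    yb <- matrix(rbinom(40, 1, 0.5), 5, 8)
    expect_equal(
      multilabel_softmargin_loss(y_pred, yb),
      oracle_loss(y_pred, yb),
      tolerance = 1e-9
    )
  }
  # extreme scores stay finite thanks to the stable form
  expect_true(is.finite(multilabel_softmargin_loss(matrix(c(-1e4, 1e4), 1), matrix(c(1, 0), 1))))
  expect_error(multilabel_softmargin_loss(matrix(0, 1, 2), matrix(c(0.5, 1), 1)), "0/1")
})

test_that("loss decreases along the negative score gradient", {
  ns <- asNamespace("fundusgcn")
  set.seed(1)
  s <- matrix(rnorm(3 * 4), 3, 4)
  y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  g <- ns$loss_grad(s, y)
  expect_lt(
    multilabel_softmargin_loss(s - 0.5 * g, y),
    multilabel_softmargin_loss(s, y)
  )
})

test_that("label thresholding is strict at confidence 0.5 (score > 0)", {
  expect_equal(predict_labels(c(0.1, -0.1, 0)), c(1, 0, 0))
  expect_equal(predict_labels(rep(1e6, 3)), rep(1, 3))
  # threshold 0.9 is score > ln 9 by logit algebra
  expect_equal(predict_labels(c(log(9) - 1e-9, log(9) + 1e-9), 0.9), c(0, 1))
})

test_that("splitting is an exact seeded partition with a patient-level option", {
  man <- tibble::tibble(
    image_path = sprintf("i%03d.png", 1:100),
    patient_id = sprintf("P%03d", ceiling(1:100 / 2))
  )
  sp <- split_dataset(man, seed = 3)
  expect_equal(as.vector(table(sp$split)), c(70, 15, 15))
  expect_identical(sp, split_dataset(man, seed = 3))
  expect_false(identical(sp$split, split_dataset(man, seed = 4)$split))
  # partition law: union is everything, pairwise disjoint
  expect_setequal(sp$image_path, man$image_path)
  expect_equal(sum(table(sp$split)), 100)
  # patient-level grouping never splits a patient across sets
  spp <- split_dataset(man, seed = 3, by_patient = TRUE)
  per_patient <- tapply(spp$split, spp$patient_id, function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
  expect_error(split_dataset(man, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("parameter groups receive their own learning rates", {
  ns <- asNamespace("fundusgcn")
  X <- random_feature_matrix(3, 4, seed = 2)
  rownames(X) <- c("a", "b", "c")
  A <- diag(3)
  cfg <- backbone_config("custom", input_size = 16, channels = c(4, 5))
  model <- ns$new_model(X, A, cfg, gcn_dims = c(4, 6, 5), seed = 2)
  state <- ns$zero_like_model(model)
  # unit gradients everywhere, no momentum/decay: step size = group lr
  grads <- list(
    backbone = list(
      stages = lapply(model$backbone$stages, function(l) list(dW = l$W * 0 + 1, db = l$b * 0 + 1)),
      down = lapply(model$backbone$down, function(l) list(dW = l$W * 0 + 1, db = l$b * 0 + 1))
    ),
    head = lapply(model$stack$W, function(W) W * 0 + 1)
  )
  opt <- optim_config(momentum = 0, weight_decay = 0, lr_backbone = 0.01, lr_head = 0.1)
  up <- ns$apply_updates(model, grads, state, opt)
  expect_equal(
    up$model$backbone$stages[[1]]$W,
    model$backbone$stages[[1]]$W - 0.01,
    tolerance = 1e-12
  )
  expect_equal(
    up$model$backbone$down[[2]]$W,
    model$backbone$down[[2]]$W - 0.01,
    tolerance = 1e-12
  )
  expect_equal(up$model$stack$W[[1]], model$stack$W[[1]] - 0.1, tolerance = 1e-12)
})

test_that("one SGD step on a fixed batch lowers the training loss", {
  ns <- asNamespace("fundusgcn")
  set.seed(6)
  X <- random_feature_matrix(4, 8, seed = 6)
  rownames(X) <- letters[1:4]
  A <- diag(4)
  cfg <- backbone_config("custom", input_size = 16, channels = c(4, 8))
  model <- ns$new_model(X, A, cfg, gcn_dims = c(8, 8, 8), seed = 6)
  xb <- array(runif(16 * 16 * 3 * 8), c(16, 16, 3, 8))
  yb <- matrix(rbinom(8 * 4, 1, 0.5), 8, 4)
  fw <- ns$model_forward(model, xb)
  before <- multilabel_softmargin_loss(fw$scores, yb)
  grads <- ns$model_backward(model, fw, ns$loss_grad(fw$scores, yb))
  opt <- optim_config(momentum = 0, weight_decay = 0, lr_backbone = 0.05, lr_head = 0.05)
  model2 <- ns$apply_updates(model, grads, ns$zero_like_model(model), opt)$model
  after <- multilabel_softmargin_loss(ns$model_forward(model2, xb)$scores, yb)
  expect_lt(after, before)
})

test_that("training is reproducible and exposes tidy/glance accessors", {
  dir <- file.path(tempdir(), "fit-repro")
  unlink(dir, recursive = TRUE)
  mix <- demo_mixture(4)
  man <- generate_dataset(40, mix, render_spec(64, 0.02, "high"), dir, seed = 21)
  man <- split_dataset(man, seed = 21)
  g <- label_graph(as.matrix(man[man$split == "train", mix$labels]))
  X <- random_feature_matrix(4, 8, seed = 21)
  rownames(X) <- mix$labels
  run <- function() {
    fit_mlgcn(
      man[man$split == "train", ], man[man$split == "validation", ],
      g, X, backbone_config("custom", input_size = 64, channels = c(8, 8, 16)),
      gcn_dims = c(8, 8, 16),
      optim = optim_config(epochs = 2), seed = 21, image_root = dir
    )
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$model$stack$W, f2$model$stack$W)
  expect_identical(f1$model$backbone$stages[[1]]$W, f2$model$backbone$stages[[1]]$W)
  expect_equal(f1$log, f2$log)
  expect_equal(nrow(tidy(f1)), 2)
  expect_named(
    glance(f1),
    c("epochs", "best_epoch", "best_val_CF1", "final_train_loss")
  )
  expect_s3_class(autoplot(f1), "ggplot")
  # prediction returns one row per manifest image with label columns
  preds <- predict(f1, man[man$split == "test", ], image_root = dir, type = "prob")
  expect_equal(nrow(preds), sum(man$split == "test"))
  expect_true(all(mix$labels %in% names(preds)))
  expect_true(all(as.matrix(preds[, mix$labels]) >= 0 & as.matrix(preds[, mix$labels]) <= 1))
})
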