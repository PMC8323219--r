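# Run configuration and the pipeline commands (simulate / build-graph /
# train / evaluate / predict). A single YAML file drives every stage; one
# global seed fans out into deterministic sub-seeds, so a rerun with the same
# config reproduces every artifact byte for byte.

config_defaults <- function() {
  list(
    out_dir = "runs/default",
    n_images = 600L,
    n_labels = 4L,
    labels = NULL, # defaults to the first n_labels lesion names
    render = list(size = 64L, noise = 0.02, contrast = "high"),
    graph = list(tau = 0.3, p = 0.25),
    embedding = list(source = "random", path = NULL, dim = 16L),
    gcn_dims = c(16L, 32L, 64L),
    backbone = list(preset = "tiny", input_size = NULL, channels = NULL),
    optim = list(
      epochs = 30L, batch_size = 8L, momentum = 0.9, weight_decay = 1e-4,
      lr_backbone = 0.01, lr_head = 0.1
    ),
    split = list(fractions = c(0.70, 0.15, 0.15), by_patient = FALSE),
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML config (or takes a list), merges it over the package
#' defaults, and rejects unknown keys so typos fail loudly rather than being
#' silently ignored.
#'
#' @param config Path to a YAML file, a list of overrides, or `NULL` for the
#'   defaults.
#' @param ... Individual overrides applied last (e.g. `seed = 7`).
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  base <- config_defaults()
  user <- if (is.character(config)) yaml::read_yaml(config) else config %||% list()
  user <- utils::modifyList(user, list(...))
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(base, user)
  for (nested in c("render", "graph", "embedding", "backbone", "optim", "split")) {
    bad <- setdiff(names(cfg[[nested]]), names(config_defaults()[[nested]]))
    if (length(bad) > 0) {
      abort(sprintf("Unknown key(s) under '%s': %s", nested, paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cfg$labels)) cfg$labels <- lesion_labels()[seq_len(cfg$n_labels)]
  cfg$n_labels <- length(cfg$labels)
  if (!cfg$embedding$source %in% c("glove_text", "random")) {
    abort("embedding$source must be 'glove_text' or 'random'.")
  }
  if (abs(sum(cfg$split$fractions) - 1) > 1e-8) abort("split fractions must sum to 1.")
  if (cfg$graph$tau <= 0 || cfg$graph$tau >= 1) abort("graph tau must be in (0, 1).")
  if (cfg$graph$p <= 0 || cfg$graph$p >= 1) abort("graph p must be in (0, 1).")
  structure(cfg, class = "run_config")
}

config_backbone <- function(cfg) {
  if (cfg$backbone$preset == "custom") {
    backbone_config("custom",
      input_size = cfg$backbone$input_size,
      channels = cfg$backbone$channels
    )
  } else {
    backbone_config(cfg$backbone$preset)
  }
}

config_embeddings <- function(cfg) {
  if (cfg$embedding$source == "glove_text") {
    tab <- load_word_vectors(cfg$embedding$path, cfg$embedding$dim)
    build_feature_matrix(cfg$labels, tab)
  } else {
    X <- random_feature_matrix(
      length(cfg$labels), cfg$embedding$dim,
      derive_seed(cfg$seed, "embedding")
    )
    rownames(X) <- cfg$labels
    X
  }
}

snapshot_config <- function(cfg, dir) {
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
}

#' Simulate a synthetic dataset (pipeline stage 1)
#'
#' Wraps [generate_dataset()] with the mixture implied by the config
#' (`demo_mixture()` for fewer than 8 labels, the clinical-shaped
#' [default_lesion_mixture()] for all 8) and prints the label marginals.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(config = NULL) {
  cfg <- run_config(config)
  mix <- if (cfg$n_labels == 8) default_lesion_mixture() else demo_mixture(cfg$n_labels)
  spec <- render_spec(cfg$render$size, cfg$render$noise, cfg$render$contrast)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- generate_dataset(cfg$n_images, mix, spec, cfg$out_dir, cfg$seed)
  snapshot_config(cfg, cfg$out_dir)
  marg <- colMeans(as.matrix(manifest[, mix$labels]))
  message(
    "Label marginals: ",
    paste(sprintf("%s=%.3f", names(marg), marg), collapse = ", ")
  )
  invisible(manifest)
}

#' Build and serialize the label graph (pipeline stage 2)
#'
#' Splits the manifest (seeded), estimates the co-occurrence graph from the
#' *training* split only, and writes every stage (`P`, `A_bin`, `A`,
#' `A_hat`) as labelled TSV files plus the split manifest.
#'
#' @inheritParams run_simulate
#' @return The `label_graph`, invisibly.
#' @export
run_build_graph <- function(config = NULL) {
  cfg <- run_config(config)
  manifest <- read_manifest(file.path(cfg$out_dir, "manifest.csv"))
  manifest <- split_dataset(manifest, cfg$split$fractions,
    seed = cfg$seed,
    by_patient = cfg$split$by_patient
  )
  readr::write_csv(manifest, file.path(cfg$out_dir, "manifest_split.csv"))
  Y <- manifest_labels(manifest[manifest$split == "train", ], cfg$labels)
  if (any(colSums(Y) == 0)) {
    abort(sprintf(
      "Label(s) absent from the training split: %s",
      paste(cfg$labels[colSums(Y) == 0], collapse = ", ")
    ))
  }
  g <- label_graph(Y, tau = cfg$graph$tau, p = cfg$graph$p)
  for (st in c("P", "A_bin", "A", "A_hat")) {
    write_matrix_tsv(g[[st]], file.path(cfg$out_dir, paste0("graph_", st, ".tsv")))
  }
  invisible(g)
}

#' Train the classifier (pipeline stage 3)
#'
#' Requires the simulate and build-graph artifacts in `out_dir`. Writes the
#' per-epoch log (`training_log.csv`) and the best-validation checkpoint
#' (`checkpoint.rds`).
#'
#' @inheritParams run_simulate
#' @param verbose Print per-epoch progress.
#' @return The `fgcn_fit`, invisibly.
#' @export
run_train <- function(config = NULL, verbose = FALSE) {
  cfg <- run_config(config)
  split_path <- file.path(cfg$out_dir, "manifest_split.csv")
  if (!file.exists(split_path)) {
    abort(sprintf("Missing '%s' — run run_build_graph() first.", split_path))
  }
  manifest <- read_manifest(split_path)
  A_hat <- read_matrix_tsv(file.path(cfg$out_dir, "graph_A_hat.tsv"))
  X <- config_embeddings(cfg)
  fit <- fit_mlgcn(
    train = manifest[manifest$split == "train", ],
    val = manifest[manifest$split == "validation", ],
    graph = A_hat, X = X,
    backbone_cfg = config_backbone(cfg), gcn_dims = cfg$gcn_dims,
    optim = do.call(optim_config, cfg$optim),
    seed = cfg$seed, image_root = cfg$out_dir, verbose = verbose
  )
  readr::write_csv(fit$log, file.path(cfg$out_dir, "training_log.csv"))
  saveRDS(fit, file.path(cfg$out_dir, "checkpoint.rds"), compress = FALSE)
  invisible(fit)
}

#' Evaluate a checkpoint on the test split (pipeline stage 4)
#'
#' Prints the per-lesion accuracy/AUC table plus OF1/CF1, and writes it as
#' `metrics.json`.
#'
#' @inheritParams run_simulate
#' @param checkpoint Optional path to a checkpoint; defaults to the one in
#'   `out_dir`.
#' @param split Which split to evaluate (default `"test"`).
#' @return The [metric_report()], invisibly.
#' @export
run_evaluate <- function(config = NULL, checkpoint = NULL, split = "test") {
  cfg <- run_config(config)
  fit <- readRDS(checkpoint %||% file.path(cfg$out_dir, "checkpoint.rds"))
  manifest <- read_manifest(file.path(cfg$out_dir, "manifest_split.csv"))
  rep <- evaluate_model(fit, manifest[manifest$split == split, ], image_root = cfg$out_dir)
  print(rep)
  write_metric_report(rep, file.path(cfg$out_dir, paste0("metrics_", split, ".json")))
  invisible(rep)
}

#' Predict scores for new images (pipeline stage 5)
#'
#' @inheritParams run_evaluate
#' @param manifest Manifest tibble (or CSV path) with `image_path`.
#' @param type Output type passed to [predict.fgcn_fit()].
#' @return Prediction tibble, invisibly (also written to `predictions.csv`).
#' @export
run_predict <- function(config = NULL, manifest = NULL, checkpoint = NULL,
                        type = "prob") {
  cfg <- run_config(config)
  fit <- readRDS(checkpoint %||% file.path(cfg$out_dir, "checkpoint.rds"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(manifest)) manifest <- read_manifest(file.path(cfg$out_dir, "manifest.csv"))
  preds <- predict(fit, manifest, image_root = cfg$out_dir, type = type)
  readr::write_csv(preds, file.path(cfg$out_dir, "predictions.csv"))
  invisible(preds)
}
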