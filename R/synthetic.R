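# Synthetic stand-in for the (private) clinical fundus dataset: correlated
# binary lesion annotations from a mixture of patient profiles, with
# closed-form conditional probabilities, plus a renderer that encodes each
# active label as a distinct visual primitive on a fundus-like disc.

#' Define a profile mixture over binary lesion labels
#'
#' Each of K patient profiles has a weight and a vector of per-label Bernoulli
#' probabilities; labels are conditionally independent within a profile, so
#' between-profile heterogeneity induces the label co-occurrence structure and
#' every conditional probability has a closed form
#' (see [true_conditional_probabilities()]).
#'
#' @param weights Length-K non-negative weights summing to 1.
#' @param probs K x N matrix of per-profile Bernoulli probabilities in \[0, 1\].
#' @param labels Length-N label names (defaults to columns of `probs`).
#' @return Object of class `profile_mixture`.
#' @export
profile_mixture <- function(weights, probs, labels = colnames(probs)) {
  probs <- as.matrix(probs)
  if (length(weights) != nrow(probs)) abort("One weight per profile is required.")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("Profile weights must be non-negative and sum to 1.")
  }
  if (any(probs < 0 | probs > 1)) abort("Profile probabilities must lie in [0, 1].")
  if (is.null(labels)) labels <- paste0("label_", seq_len(ncol(probs)))
  colnames(probs) <- labels
  structure(
    list(weights = weights, probs = probs, labels = labels),
    class = "profile_mixture"
  )
}

#' Default 8-lesion mixture
#'
#' Three patient profiles — largely healthy, vascular retinopathy, and
#' severe multi-lesion disease — with near-deterministic within-profile
#' rates. The mixture preserves the rank order of lesion frequencies seen in
#' clinical screening cohorts (arteriosclerosis and hemorrhages most common,
#' laser scars least), but compresses the dynamic range upward: every
#' marginal stays above ~0.35 so that all conditional co-occurrence
#' probabilities are estimable from a few thousand annotations — lesions at
#' true clinical rarity (a few percent) leave too few conditioning samples
#' for the graph-recovery tolerance the package tests itself against (see
#' the methods vignette).
#'
#' @return A [profile_mixture()] over the 8 canonical lesion labels.
#' @export
default_lesion_mixture <- function() {
  q <- rbind(
    healthy = c(0.03, 0.04, 0.05, 0.06, 0.08, 0.05, 0.06, 0.04),
    vascular = c(0.05, 0.07, 0.07, 0.93, 0.97, 0.88, 0.92, 0.07),
    severe = c(0.85, 0.92, 0.94, 0.96, 0.98, 0.90, 0.94, 0.88)
  )
  colnames(q) <- lesion_labels()
  profile_mixture(weights = c(0.25, 0.35, 0.40), probs = q)
}

#' Small correlated mixture for fast end-to-end experiments
#'
#' Two equally weighted profiles over `n_labels` labels: the first half of the
#' labels is frequent (0.9) in profile 1 and rare (0.1) in profile 2, and
#' vice versa, producing strong positive co-occurrence within each half.
#'
#' @param n_labels Number of labels (default 4).
#' @return A [profile_mixture()].
#' @export
demo_mixture <- function(n_labels = 4L) {
  stopifnot(n_labels >= 2)
  half <- ceiling(n_labels / 2)
  q1 <- c(rep(0.9, half), rep(0.1, n_labels - half))
  q <- rbind(q1, rev(q1))
  colnames(q) <- lesion_labels()[seq_len(n_labels)]
  profile_mixture(weights = c(0.5, 0.5), probs = q)
}

#' Sample correlated binary label annotations
#'
#' Each sample draws a profile with probability proportional to the weights,
#' then each label independently from that profile's Bernoulli rate.
#'
#' @param n Number of samples.
#' @param mix A [profile_mixture()].
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return n x N binary matrix with label column names.
#' @export
sample_labels <- function(n, mix, seed = 1L) {
  stopifnot(n >= 1)
  if (!inherits(mix, "profile_mixture")) abort("`mix` must be a profile_mixture.")
  with_seed(seed, {
    k <- sample.int(nrow(mix$probs), n, replace = TRUE, prob = mix$weights)
    U <- matrix(stats::runif(n * ncol(mix$probs)), n)
    Y <- (U < mix$probs[k, , drop = FALSE]) + 0
    colnames(Y) <- mix$labels
    Y
  })
}

#' Closed-form conditional probabilities of a profile mixture
#'
#' Within a profile labels are independent, so the joint probability of a
#' label pair is `sum_k w_k q_ki q_kj` and
#' `P(L_i | L_j) = sum_k w_k q_ki q_kj / sum_k w_k q_kj` for `i != j`; the
#' diagonal is 1 by definition. This is the exact oracle against which the
#' empirical graph construction is checked.
#'
#' @param mix A [profile_mixture()].
#' @return N x N conditional-probability matrix.
#' @export
true_conditional_probabilities <- function(mix) {
  q <- mix$probs
  w <- mix$weights
  marg <- colSums(w * q)
  if (any(marg <= 0)) {
    abort(sprintf(
      "Label(s) with zero marginal probability: %s",
      paste(mix$labels[marg <= 0], collapse = ", ")
    ))
  }
  joint <- t(q) %*% (w * q) # joint[i, j] = sum_k w_k q_ki q_kj
  P <- sweep(joint, 2, marg, "/")
  diag(P) <- 1
  dimnames(P) <- list(mix$labels, mix$labels)
  P
}

#' Rendering parameters for synthetic fundus images
#'
#' @param size Square image side in pixels (>= 32; tests use 64, larger
#'   production-like sizes work unchanged).
#' @param noise Standard deviation of additive Gaussian pixel noise.
#' @param contrast `"high"` places each label's primitive in its own sector
#'   with saturated colours (trivially learnable); `"soft"` scatters fainter
#'   primitives over the disc.
#' @return Object of class `render_spec`.
#' @export
render_spec <- function(size = 64L, noise = 0.02, contrast = c("high", "soft")) {
  contrast <- match.arg(contrast)
  if (size < 32) abort("Minimum image size is 32 pixels.")
  structure(
    list(size = as.integer(size), noise = noise, contrast = contrast),
    class = "render_spec"
  )
}

# paint a (possibly fuzzy) disc of colour `col` onto the image
add_blob <- function(img, xx, yy, x0, y0, rad, col, alpha = 1, fuzzy = FALSE) {
  d2 <- (xx - x0)^2 + (yy - y0)^2
  if (fuzzy) {
    wgt <- alpha * exp(-d2 / (2 * (rad / 1.5)^2))
    wgt[d2 > (2.5 * rad)^2] <- 0
  } else {
    wgt <- alpha * (d2 <= rad^2)
  }
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - wgt) + col[ch] * wgt
  }
  img
}

add_stroke <- function(img, xx, yy, x0, y0, angle, len, width, col, alpha = 1) {
  ux <- cos(angle)
  uy <- sin(angle)
  tpar <- (xx - x0) * ux + (yy - y0) * uy
  perp <- abs(-(xx - x0) * uy + (yy - y0) * ux)
  wgt <- alpha * (abs(tpar) <= len / 2 & perp <= width / 2)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - wgt) + col[ch] * wgt
  }
  img
}

#' Render one synthetic fundus image
#'
#' Draws a circular fundus-like background, then one visual primitive family
#' per active label — dot rings for laser scars, yellow specks for drusen, a
#' bright inner disc for an enlarged cup, dark blotches for hemorrhages,
#' thick bright strokes for arteriosclerosis, tiny red dots for
#' microaneurysms, bright yellow blobs for hard exudates, pale fuzzy patches
#' for soft exudates — and finally additive Gaussian noise. The output is a
#' pure function of `(labels, spec, seed)`.
#'
#' @param labels Binary vector (length N <= 8) of active lesions.
#' @param spec A [render_spec()].
#' @param seed Integer seed for primitive placement and noise.
#' @return (size, size, 3) array of RGB values in \[0, 1\].
#' @export
render_image <- function(labels, spec, seed = 1L) {
  n_lab <- length(labels)
  if (n_lab < 1 || n_lab > 8) abort("Between 1 and 8 labels are supported.")
  s <- spec$size
  xx <- matrix(rep(seq_len(s), each = s), s)
  yy <- matrix(rep(seq_len(s), times = s), s)
  c0 <- (s + 1) / 2
  R <- 0.48 * s
  d2 <- (xx - c0)^2 + (yy - c0)^2
  inside <- d2 <= R^2
  shade <- 1 - 0.35 * d2 / R^2
  img <- array(0, c(s, s, 3))
  img[, , 1] <- 0.62 * shade * inside
  img[, , 2] <- 0.30 * shade * inside
  img[, , 3] <- 0.10 * shade * inside

  high <- spec$contrast == "high"
  with_seed(seed, {
    for (i in seq_len(n_lab)) {
      if (labels[i] == 0) next
      # each label owns an angular sector in high-contrast mode
      theta <- 2 * pi * (i - 0.5) / n_lab
      bx <- c0 + 0.26 * s * cos(theta)
      by <- c0 + 0.26 * s * sin(theta)
      jit <- function(sc = 0.04) stats::runif(1, -sc * s, sc * s)
      place <- function() {
        if (high) {
          c(bx + jit(0.02), by + jit(0.02))
        } else {
          ang <- stats::runif(1, 0, 2 * pi)
          rr <- stats::runif(1, 0, 0.38 * s)
          c(c0 + rr * cos(ang), c0 + rr * sin(ang))
        }
      }
      a <- if (high) 1 else 0.75
      img <- switch(i,
        { # laser scars: ring of small dark dots
          ctr <- place()
          for (t in seq(0, 2 * pi, length.out = 9)[-9]) {
            img <- add_blob(
              img, xx, yy, ctr[1] + 0.10 * s * cos(t), ctr[2] + 0.10 * s * sin(t),
              0.022 * s, c(0.25, 0.12, 0.05), a
            )
          }
          img
        },
        { # drusen: scattered yellow specks
          for (k in 1:6) {
            ctr <- place()
            img <- add_blob(img, xx, yy, ctr[1] + jit(), ctr[2] + jit(), 0.018 * s,
              c(0.95, 0.85, 0.30), a)
          }
          img
        },
        { # enlarged cup-disc ratio: bright inner disc
          ctr <- place()
          img <- add_blob(img, xx, yy, ctr[1], ctr[2], 0.12 * s, c(0.98, 0.85, 0.55), a)
          img <- add_blob(img, xx, yy, ctr[1], ctr[2], 0.07 * s, c(1.00, 0.97, 0.80), a)
          img
        },
        { # hemorrhages: dark red blotches
          for (k in 1:3) {
            ctr <- place()
            img <- add_blob(img, xx, yy, ctr[1] + jit(), ctr[2] + jit(),
              stats::runif(1, 0.035, 0.055) * s, c(0.30, 0.02, 0.02), a)
          }
          img
        },
        { # arteriosclerosis: thickened bright vessel strokes
          ctr <- place()
          for (k in 1:2) {
            img <- add_stroke(
              img, xx, yy, ctr[1] + jit(), ctr[2] + jit(),
              stats::runif(1, 0, pi), 0.28 * s, 0.030 * s, c(0.95, 0.65, 0.45), a
            )
          }
          img
        },
        { # microaneurysms: tiny red dots
          for (k in 1:8) {
            ctr <- place()
            img <- add_blob(img, xx, yy, ctr[1] + jit(), ctr[2] + jit(), 0.012 * s,
              c(0.75, 0.05, 0.05), a)
          }
          img
        },
        { # hard exudates: bright yellow blobs
          for (k in 1:4) {
            ctr <- place()
            img <- add_blob(img, xx, yy, ctr[1] + jit(), ctr[2] + jit(),
              stats::runif(1, 0.025, 0.040) * s, c(1.00, 0.95, 0.20), a)
          }
          img
        },
        { # soft exudates: pale fuzzy patches
          for (k in 1:2) {
            ctr <- place()
            img <- add_blob(img, xx, yy, ctr[1] + jit(), ctr[2] + jit(), 0.06 * s,
              c(0.92, 0.90, 0.82), 0.85 * a, fuzzy = TRUE)
          }
          img
        }
      )
    }
    if (spec$noise > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise), dim(img))
    }
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic dataset on disk
#'
#' Samples `n` annotation vectors from the mixture, renders one PNG per
#' sample, and writes a `manifest.csv` with columns `image_path`,
#' `patient_id`, `eye` and one binary column per label. Consecutive images
#' share a patient id (two eyes per patient) so patient-level splitting is
#' exercisable. Fully reproducible per seed.
#'
#' @param n Number of images.
#' @param mix A [profile_mixture()].
#' @param spec A [render_spec()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return The manifest tibble (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n, mix, spec = render_spec(), out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  Y <- sample_labels(n, mix, derive_seed(seed, "labels"))
  paths <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    img <- render_image(Y[i, ], spec, derive_seed(seed, paste0("image", i)))
    png::writePNG(img, file.path(out_dir, paths[i]))
  }
  manifest <- dplyr::bind_cols(
    tibble(
      image_path = paths,
      patient_id = sprintf("P%05d", ceiling(seq_len(n) / 2)),
      eye = ifelse(seq_len(n) %% 2 == 1, "OD", "OS")
    ),
    as_tibble(Y)
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.csv` written by [generate_dataset()].
#' @return Manifest tibble; image paths stay relative to the manifest's
#'   directory (use `attr(x, "image_root")`).
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  attr(m, "image_root") <- dirname(path)
  m
}
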