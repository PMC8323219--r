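#' Load word vectors from a GloVe-style text file
#'
#' Reads plain-text word vectors: one token per line followed by `d`
#' whitespace-separated numbers. Both common dialects are accepted — the bare
#' GloVe layout and the word2vec text layout whose first line is a
#' `"<n_vectors> <dim>"` header (detected and skipped automatically).
#'
#' @param path Path to the vector file (UTF-8).
#' @param expected_dim Optional positive integer; if given, an error is raised
#'   unless the file's vectors have exactly this dimension.
#' @return A named list of numeric vectors (one per token), with attribute
#'   `d` giving the shared embedding dimension.
#' @export
load_word_vectors <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) abort(sprintf("Word-vector file not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("Word-vector file is empty: '%s'", path))

  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  # word2vec text dialect: a two-integer "<count> <dim>" header line
  if (length(first) == 2 && !anyNA(suppressWarnings(as.integer(first))) &&
    all(as.numeric(first) == round(as.numeric(first)))) {
    lines <- lines[-1]
    if (length(lines) == 0) abort(sprintf("Word-vector file has only a header: '%s'", path))
  }

  parts <- strsplit(trimws(lines), "\\s+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  vecs <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))

  dims <- lengths(vecs)
  d <- dims[[1]]
  if (d < 1) abort("First vector line has no numeric entries.")
  bad <- which(dims != d | vapply(vecs, anyNA, logical(1)))
  if (length(bad) > 0) {
    abort(sprintf(
      "Inconsistent vector dimensions in '%s': line %d ('%s') has %d values, expected %d.",
      path, bad[[1]], tokens[[bad[[1]]]], dims[[bad[[1]]]], d
    ))
  }
  if (!is.null(expected_dim) && d != expected_dim) {
    abort(sprintf("Vectors in '%s' have dimension %d, expected %d.", path, d, expected_dim))
  }
  if (anyDuplicated(tokens)) {
    abort(sprintf("Duplicate token '%s' in '%s'.", tokens[duplicated(tokens)][[1]], path))
  }
  names(vecs) <- tokens
  attr(vecs, "d") <- d
  class(vecs) <- "word_vector_table"
  vecs
}

#' Compose one label's embedding from its tokens
#'
#' Lowercases the label, splits it on whitespace, looks every token up in the
#' word-vector table and returns the mean of the vectors found. Tokens absent
#' from the table are skipped with a warning; if no token is found the call
#' errors, so a label can never silently become a zero vector.
#'
#' @param label Non-empty label string (may be multi-word, e.g. "hard exudates").
#' @param table A `word_vector_table` from [load_word_vectors()].
#' @return Numeric vector of length `attr(table, "d")`.
#' @export
compose_label_vector <- function(label, table) {
  if (!nzchar(trimws(label))) abort("`label` must be a non-empty string.")
  toks <- strsplit(tolower(trimws(label)), "\\s+")[[1]]
  found <- toks[toks %in% names(table)]
  missing <- setdiff(toks, found)
  if (length(found) == 0) {
    abort(sprintf(
      "No token of label '%s' found in the word-vector table (missing: %s).",
      label, paste(missing, collapse = ", ")
    ))
  }
  if (length(missing) > 0) {
    warn(sprintf(
      "Label '%s': token(s) not in vocabulary, skipped: %s",
      label, paste(missing, collapse = ", ")
    ))
  }
  vecs <- do.call(rbind, table[found])
  colMeans(vecs)
}

#' Build the N x d label feature matrix
#'
#' Stacks [compose_label_vector()] over an ordered list of label names. Row
#' order is the canonical label order used by the adjacency matrix, the GCN
#' and every metric report.
#'
#' @param labels Character vector of unique label names (N >= 1).
#' @param table A `word_vector_table`.
#' @return N x d numeric matrix with `labels` as rownames.
#' @export
build_feature_matrix <- function(labels, table) {
  if (length(labels) < 1) abort("Need at least one label.")
  if (anyDuplicated(labels)) {
    abort(sprintf("Duplicate label name: '%s'.", labels[duplicated(labels)][[1]]))
  }
  rows <- lapply(labels, function(lb) {
    tryCatch(compose_label_vector(lb, table), error = function(e) {
      abort(sprintf("Failed to embed label '%s': %s", lb, conditionMessage(e)))
    })
  })
  X <- do.call(rbind, rows)
  rownames(X) <- labels
  X
}

#' Random Gaussian label feature matrix
#'
#' Baseline feature matrix with i.i.d. standard-normal entries, used as a
#' control against corpus-trained embeddings. Deterministic per seed.
#'
#' @param n_labels Number of labels N.
#' @param dim Embedding dimension d (300 in the production configuration).
#' @param seed Integer seed.
#' @return N x d numeric matrix.
#' @export
random_feature_matrix <- function(n_labels, dim, seed) {
  stopifnot(n_labels > 0, dim > 0)
  with_seed(seed, matrix(stats::rnorm(n_labels * dim), nrow = n_labels, ncol = dim))
}
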