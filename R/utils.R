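#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

#' Canonical lesion label names
#'
#' The eight fundus lesion categories the model detects, in the fixed order
#' used for every label matrix, adjacency matrix and metric report in the
#' package.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' lesion_labels()
lesion_labels <- function() {
  c(
    "laser scars", "drusen", "cup disc ratio", "hemorrhages",
    "retinal arteriosclerosis", "microaneurysms", "hard exudates",
    "soft exudates"
  )
}

# Deterministic sub-seed derived from one global seed and a purpose tag, so a
# single --seed knob fans out to independent streams (split / init / sampling)
# without coupling them. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647L)
}

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_binary_matrix <- function(Y, arg = "Y") {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (!is.numeric(Y)) abort(sprintf("`%s` must be a numeric binary matrix.", arg))
  if (!all(Y %in% c(0, 1))) {
    abort(sprintf("`%s` must contain only 0/1 entries.", arg))
  }
  Y
}

sigmoid <- function(x) 1 / (1 + exp(-x))
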