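# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a sub-stream seed from a master seed; keeps the result a valid
# 32-bit integer so independent generator stages do not perturb each other.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7L + offset) %% 2147483629)
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Construct an abundance matrix with an explicit scale flag
#'
#' Abundance matrices in this package are plain numeric matrices (features in
#' rows, samples in columns) carrying a `"scale"` attribute, either
#' `"linear"` (non-negative peak areas) or `"log2"`.
#'
#' @param x numeric matrix with rownames (features) and colnames (samples).
#' @param scale `"linear"` or `"log2"`.
#' @return the matrix with its scale attribute set.
#' @export
abundance_matrix <- function(x, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stop_if_not(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  stop_if_not(!anyNA(x), "abundance matrix must not contain missing cells")
  if (scale == "linear") {
    stop_if_not(all(x >= 0), "linear-scale abundances must be non-negative")
  }
  attr(x, "scale") <- scale
  x
}

#' @rdname abundance_matrix
#' @export
matrix_scale <- function(x) attr(x, "scale") %||% "linear"

#' Convert an abundance matrix to log2 scale
#'
#' @param x abundance matrix (see [abundance_matrix()]).
#' @return the matrix on log2 scale.
#' @export
to_log2 <- function(x) {
  if (identical(matrix_scale(x), "log2")) return(x)
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "cannot log-transform non-positive value at feature '%s', sample '%s'",
      rownames(x)[bad[1L]] %||% bad[1L], colnames(x)[bad[2L]] %||% bad[2L]
    ), call. = FALSE)
  }
  abundance_matrix(log2(x), "log2")
}

#' @rdname to_log2
#' @export
to_linear <- function(x) {
  if (identical(matrix_scale(x), "linear")) return(x)
  abundance_matrix(2^x, "linear")
}

# Precursor identity: sequence + modifications + charge, as a single key.
precursor_key <- function(sequence, modifications, charge) {
  paste(sequence, modifications, charge, sep = "|")
}

report_precursor_keys <- function(report) {
  precursor_key(report$sequence, report$modifications, report$charge)
}
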