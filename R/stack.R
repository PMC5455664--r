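#' Ordered stack of feature layers
#'
#' Collects band images and correlation maps that share one grid into an
#' ordered, uniquely named stack — the joint input to redundancy filtering
#' and clustering. Stack order matters: it is the scan order of
#' [remove_redundant()] and the column order of [to_feature_matrix()].
#'
#' @param layers A list of `feature_layer` objects (or several layers given
#'   as `...`).
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers) {
  if (inherits(layers, "feature_layer")) layers <- list(layers)
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "feature_layer"))) {
    abort("`layers` must be a non-empty list of feature_layer objects.")
  }
  dims <- vapply(layers, function(l) dim(l$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All layers must share one grid.")
  }
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) abort("Layer names must be unique.")
  names(layers) <- nm
  structure(list(layers = layers,
                 rows = dims[1, 1], cols = dims[2, 1]),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack: %d layers on %d x %d>\n",
              length(x$layers), x$rows, x$cols))
  for (l in x$layers) cat(sprintf("  - %s (%s)\n", l$name, l$kind))
  invisible(x)
}

#' @export
length.layer_stack <- function(x) length(x$layers)

#' @export
names.layer_stack <- function(x) names(x$layers)

#' Pairwise Pearson correlation matrix of a layer stack
#'
#' Entry (i, j) is the Pearson coefficient of correlation between the
#' flattened 0--255 values of layers i and j; the diagonal is 1. A constant
#' layer has no defined correlation: its entries are set to 0 and its name
#' is reported in the `constant` attribute.
#'
#' @param stack A [layer_stack] with at least 2 layers.
#' @return A symmetric numeric matrix with layer names as dimnames.
#' @export
layer_coc_matrix <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  if (length(stack) < 2) abort("Need at least 2 layers.")
  X <- vapply(stack$layers, function(l) as.numeric(flatten_image(l$values)),
              numeric(stack$rows * stack$cols))
  const <- apply(X, 2, function(v) all(v == v[1]))
  suppressWarnings(C <- cor(X))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  dimnames(C) <- list(names(stack), names(stack))
  attr(C, "constant") <- names(stack)[const]
  C
}

#' Remove redundant layers by pairwise correlation
#'
#' Layer pairs with `|COC| > threshold` carry redundant information; one
#' element of each pair is removed. The scan is deterministic and greedy in
#' stack order: for each surviving layer i (front to back), any later layer
#' j with `|COC(i, j)| > threshold` is dropped and logged against i. After
#' the scan no surviving pair exceeds the threshold, and re-applying the
#' filter changes nothing.
#'
#' @param stack A [layer_stack].
#' @param threshold Absolute COC above which a pair is redundant, in (0, 1);
#'   default 0.9.
#' @return A list with elements `stack` (the filtered [layer_stack]) and
#'   `removal_log`, a tibble with columns `removed`, `partner` and `coc`.
#' @export
remove_redundant <- function(stack, threshold = 0.9) {
  stopifnot(inherits(stack, "layer_stack"))
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  n <- length(stack)
  log <- tibble(removed = character(), partner = character(), coc = double())
  if (n >= 2) {
    C <- layer_coc_matrix(stack)
    keep <- rep(TRUE, n)
    for (i in seq_len(n - 1)) {
      if (!keep[i]) next
      for (j in seq(i + 1, n)) {
        if (keep[j] && abs(C[i, j]) > threshold) {
          keep[j] <- FALSE
          log <- dplyr::add_row(log, removed = names(stack)[j],
                                partner = names(stack)[i], coc = C[i, j])
        }
      }
    }
    stack <- layer_stack(stack$layers[keep])
  }
  list(stack = stack, removal_log = log)
}

#' Raw data matrix of a layer stack
#'
#' Vectorizes every layer (row-major pixel order) and binds the vectors as
#' columns: the `n_pixels x n_layers` raw data matrix of 0--255 gray values
#' on which pixel clustering operates. The transformation is invertible
#' given the grid shape.
#'
#' @param stack A [layer_stack].
#' @return An integer matrix, one row per pixel, one named column per layer.
#' @export
to_feature_matrix <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  X <- vapply(stack$layers, function(l) flatten_image(l$values),
              integer(stack$rows * stack$cols))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(stack)))
  colnames(X) <- names(stack)
  X
}
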