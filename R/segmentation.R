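#' Pairwise Euclidean distances between pixel feature vectors
#'
#' Thin wrapper around [stats::dist()] returning the condensed set of all
#' n(n-1)/2 Euclidean distances between the rows of the raw data matrix.
#'
#' @param features Numeric matrix, one row per pixel (see
#'   [to_feature_matrix()]). Columns are not re-standardized: all layers
#'   already share the 0--255 scale.
#' @return A `"dist"` object.
#' @export
pairwise_euclidean <- function(features) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) abort("`features` must be finite.")
  dist(features, method = "euclidean")
}

#' UPGMA (unweighted average linkage) dendrogram
#'
#' Agglomerative hierarchical clustering where the distance between two
#' clusters is the unweighted average of all cross-pair leaf distances
#' (UPGMA). Merge heights are monotone non-decreasing. Computed by
#' [stats::hclust()] with `method = "average"`.
#'
#' @param distances A `"dist"` object (see [pairwise_euclidean()]).
#' @return An object of classes `upgma_dendrogram` and `hclust`; usual
#'   `hclust` components (`merge`, `height`, `order`, ...) apply.
#' @export
upgma_linkage <- function(distances) {
  if (!inherits(distances, "dist")) abort("`distances` must be a dist object.")
  n <- attr(distances, "Size")
  if (n < 2) abort("Need at least 2 leaves to build a dendrogram.")
  hc <- hclust(distances, method = "average")
  class(hc) <- c("upgma_dendrogram", "hclust")
  hc
}

#' Cut a dendrogram at a fraction of its total distance
#'
#' The total (Euclidean) distance of a dendrogram is its maximum merge
#' height (the root height). Cutting at `fraction` of that height groups
#' the leaves into the clusters existing strictly below the cut, mirroring
#' a horizontal threshold drawn through the displayed tree. Thresholds
#' around 0.55--0.57 avoid over- and under-segmentation for typical bone
#' maps; the value is a per-dataset tuning choice.
#'
#' @param d An `hclust`-like dendrogram (see [upgma_linkage()]).
#' @param fraction Cut position as a proportion of the root height, in
#'   (0, 1).
#' @return Integer cluster labels, one per leaf, with attributes
#'   `cut_height` and `fraction`. A degenerate dendrogram (all merge
#'   heights 0) yields a single cluster.
#' @export
cut_at_fraction <- function(d, fraction) {
  stopifnot(inherits(d, "hclust"))
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  total <- max(d$height)
  if (total <= 0) {
    labels <- rep(1L, length(d$order))
    cut_height <- 0
  } else {
    cut_height <- fraction * total
    # merges at exactly the cut height stay above it ("strictly below")
    labels <- as.integer(cutree(d, h = cut_height * (1 - 1e-12)))
  }
  structure(labels, cut_height = cut_height, fraction = fraction)
}

#' Reconstruct a segmented image from leaf labels
#'
#' Reshapes per-leaf cluster labels back onto the map grid (row-major pixel
#' order), renumbers segments by descending size and flags segments smaller
#' than `min_segment_size` as faulty-measurement candidates (poor-SNR
#' pixels tend to end up in small stray clusters). Flagged segments are
#' kept, not merged away.
#'
#' @param leaf_labels Integer cluster labels, one per pixel (length must be
#'   `rows * cols`).
#' @param grid `c(rows, cols)` of the map.
#' @param min_segment_size Segments with fewer pixels are flagged (default
#'   20).
#' @param cut_fraction,cut_height Optional provenance carried from
#'   [cut_at_fraction()]; filled from the attributes of `leaf_labels` when
#'   present.
#' @return An object of class `segmentation_result` with elements `labels`
#'   (integer `rows x cols` matrix, values `1..n_segments`), `n_segments`,
#'   `segment_sizes`, `small_segment` (logical per segment), `cut_fraction`
#'   and `cut_height`.
#' @export
labels_to_image <- function(leaf_labels, grid, min_segment_size = 20,
                            cut_fraction = NULL, cut_height = NULL) {
  rows <- grid[1]; cols <- grid[2]
  if (length(leaf_labels) != rows * cols) {
    abort(sprintf("Got %d labels for a %d x %d grid.",
                  length(leaf_labels), rows, cols))
  }
  cut_fraction <- cut_fraction %||% attr(leaf_labels, "fraction")
  cut_height <- cut_height %||% attr(leaf_labels, "cut_height")
  lab <- as.integer(leaf_labels)
  sizes <- sort(table(lab), decreasing = TRUE)
  remap <- setNames(seq_along(sizes), names(sizes))
  lab <- remap[as.character(lab)]
  sizes <- as.integer(sizes)
  structure(
    list(labels = unflatten_image(as.integer(lab), rows, cols),
         n_segments = length(sizes),
         segment_sizes = sizes,
         small_segment = sizes < min_segment_size,
         min_segment_size = min_segment_size,
         cut_fraction = cut_fraction, cut_height = cut_height),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %d x %d, %d segments (%d flagged small)>\n",
              nrow(x$labels), ncol(x$labels), x$n_segments,
              sum(x$small_segment)))
  invisible(x)
}

#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble(segment = seq_len(x$n_segments),
         size = x$segment_sizes,
         small_segment = x$small_segment)
}

#' Segment a layer stack by hierarchical clustering
#'
#' Convenience wrapper chaining [to_feature_matrix()],
#' [pairwise_euclidean()], [upgma_linkage()], [cut_at_fraction()] and
#' [labels_to_image()].
#'
#' @param stack A [layer_stack] (after redundancy filtering).
#' @param cut_fraction Fraction of the total distance at which the
#'   dendrogram is cut (default 0.57).
#' @param min_segment_size Passed to [labels_to_image()].
#' @return A list with elements `segmentation` (a `segmentation_result`)
#'   and `dendrogram` (the `upgma_dendrogram`).
#' @export
segment_map <- function(stack, cut_fraction = 0.57, min_segment_size = 20) {
  X <- to_feature_matrix(stack)
  dend <- upgma_linkage(pairwise_euclidean(X))
  labels <- cut_at_fraction(dend, cut_fraction)
  seg <- labels_to_image(labels, c(stack$rows, stack$cols),
                         min_segment_size = min_segment_size)
  list(segmentation = seg, dendrogram = dend)
}
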