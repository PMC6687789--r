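#' Ward.D2 hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the minimum-variance (Ward) criterion in
#' the Murtagh-Legendre "Ward.D2" formulation: the Lance-Williams update is
#' applied to squared dissimilarities and merge heights are reported on the
#' original (square-rooted) scale. Ward linkage produces the compact,
#' roughly spherical clusters appropriate for both the encoded-shape and the
#' magnitude step. This wraps [stats::hclust()] after validating the input.
#'
#' @param d A `dist` object or symmetric non-negative matrix.
#' @return An object of class `hclust`. Heights are non-decreasing across
#'   merges (Ward is reducible, so no inversions occur).
#' @export
ward_linkage <- function(d) {
  d <- as_distance_object(d)
  if (attr(d, "Size") < 2) stop_validation("at least 2 items are required")
  hc <- stats::hclust(d, method = "ward.D2")
  hc
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last k - 1 merges and relabels clusters in order of first
#' appearance, so cluster 1 always contains the first item.
#'
#' @param hc An `hclust` object.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Integer vector of cluster labels named by item id.
#' @export
cut_clusters <- function(hc, k) {
  n <- length(hc$order)
  if (!is_scalar_number(k) || k < 1 || k > n) {
    stop_validation("k must be between 1 and %d, got %s", n, format(k))
  }
  raw <- stats::cutree(hc, k = as.integer(k))
  relabel_first_appearance(raw)
}

# relabel an integer partition so labels appear in increasing order of the
# first index carrying them
relabel_first_appearance <- function(labels) {
  out <- match(labels, unique(labels))
  names(out) <- names(labels)
  out
}

# merge table of an hclust fit for serialisation: one row per merge with the
# children (negative = leaf index), height, and resulting cluster size
linkage_tibble <- function(hc) {
  sizes <- integer(nrow(hc$merge))
  size_of <- function(node, i) {
    if (node < 0) 1L else sizes[node]
  }
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- size_of(hc$merge[i, 1], i) + size_of(hc$merge[i, 2], i)
  }
  tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1],
    right = hc$merge[, 2],
    height = hc$height,
    size = sizes
  )
}
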