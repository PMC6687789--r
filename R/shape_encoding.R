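#' Encode a curve as the signs of its first differences
#'
#' Reduces a curve of length L to a ternary sequence of length L - 1: +1 where
#' the next sample is higher than the previous one, -1 where it is lower, and
#' (by default) 0 where the two are exactly equal. This strips all magnitude
#' information and keeps only the waveform's direction changes, which is what
#' the shape-clustering step operates on. The encoding is invariant to
#' positive scaling and to offsets, and antisymmetric under negation.
#'
#' Exact ties can arise from linear interpolation; `ties = "zero"` keeps them
#' neutral in the metric, `ties = "up"` codes non-decreasing steps as +1.
#'
#' @param x Numeric vector, length >= 2.
#' @param ties How to code zero differences: `"zero"` (default) or `"up"`.
#' @return Numeric vector over \{-1, 0, +1\} of length `length(x) - 1`.
#' @examples
#' encode_signs(c(0.1, 0.3, 0.2))  # +1 -1
#' @export
encode_signs <- function(x, ties = c("zero", "up")) {
  ties <- match.arg(ties)
  if (length(x) < 2) stop_validation("cannot encode a series shorter than 2 samples")
  if (anyNA(x)) stop_validation("series contains missing values")
  s <- sign(diff(x))
  if (ties == "up") s[s == 0] <- 1
  s
}

#' Euclidean distance matrix between equal-length vectors
#'
#' Builds the pairwise Euclidean distance object used by both clustering
#' steps (encoded waveforms for shape, Nm/kg curves for magnitude).
#'
#' @param items A list of equal-length numeric vectors or a matrix with one
#'   item per row.
#' @param ids Item identifiers used as labels; defaults to list/row names.
#' @return A [stats::dist] object with `Labels` set to `ids`.
#' @export
distance_matrix <- function(items, ids = NULL) {
  if (is.matrix(items)) {
    m <- items
    ids <- ids %||% rownames(m)
  } else {
    len <- lengths(items)
    if (length(unique(len)) != 1) {
      bad <- which(len != stats::median(len))
      stop_validation("items %s have lengths differing from the rest",
                      paste(utils::head(bad, 5), collapse = ", "))
    }
    ids <- ids %||% names(items)
    m <- do.call(rbind, items)
  }
  if (nrow(m) < 2) stop_validation("at least 2 items are required")
  d <- stats::dist(m, method = "euclidean")
  attr(d, "Labels") <- ids %||% as.character(seq_len(nrow(m)))
  d
}

#' Write a distance matrix as a square CSV with an id header row/column
#'
#' @param d A `dist` object or square matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  d <- as_distance_object(d)
  m <- as.matrix(d)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- dist_ids(d)
  df <- dplyr::bind_cols(tibble(id = dist_ids(d)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
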