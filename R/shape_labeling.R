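#' Shape and magnitude label sets
#'
#' The six waveform shape families and three magnitude classes the pipeline
#' assigns. Shapes describe the early-stance valgus moment waveform: bumps
#' (peaks/troughs, early or late within the analysis window) and monotone
#' slopes (up/down). Magnitudes rank Nm/kg sub-clusters within a shape.
#'
#' @return Character vector of levels.
#' @export
shape_levels <- function() {
  c("early_peak", "peak", "upslope", "downslope", "trough", "early_trough")
}

#' @rdname shape_levels
#' @export
magnitude_levels <- function() {
  c("small", "medium", "large")
}

#' Profile a cluster of curves
#'
#' Summarises a set of equal-length member curves by their pointwise mean and
#' the geometry used by [classify_shape()]: the apex (the interior point
#' deviating most from the chord joining the endpoints), its sign, the net
#' change over the window, and the prominence (apex deviation relative to
#' the curve's range).
#'
#' @param curves List of equal-length numeric vectors or a matrix with one
#'   curve per row.
#' @return A list of class `vm_profile`: `mean_curve`, `apex_index`,
#'   `apex_sign`, `net_change`, `prominence`, `n_members`.
#' @export
profile_cluster <- function(curves) {
  if (is.matrix(curves)) m <- curves else m <- curve_matrix(curves)
  if (nrow(m) == 0) stop_validation("no member curves")
  mean_curve <- colMeans(m)
  L <- length(mean_curve)
  chord <- seq(mean_curve[1], mean_curve[L], length.out = L)
  dev <- mean_curve - chord
  apex_index <- which.max(abs(dev))
  apex_dev <- dev[apex_index]
  rng <- diff(range(mean_curve))
  structure(
    list(
      mean_curve = mean_curve,
      apex_index = apex_index,
      apex_sign = sign(apex_dev),
      net_change = mean_curve[L] - mean_curve[1],
      prominence = if (rng > 0) abs(apex_dev) / rng else 0,
      n_members = nrow(m)
    ),
    class = "vm_profile"
  )
}

#' Classify a cluster profile into one of the six shape families
#'
#' Quantitative stand-in for visual inspection of aggregate cluster curves.
#' A profile with a prominent apex (prominence at or above `prominence_min`)
#' is a bump: positive apex gives `early_peak` when the apex falls within the
#' first `early_fraction` of the window, otherwise `peak`; negative apex
#' gives `early_trough`/`trough` by the same timing rule. Profiles without a
#' prominent apex are monotone slopes, labelled by the sign of the net
#' change. The rule is invariant to positive rescaling of the curve.
#'
#' The default `early_fraction = 0.5` places the early/late boundary at half
#' the 30 percent stance window, i.e. 15 percent of stance, bracketing the
#' observation that early peaks fall within the first quarter of stance.
#'
#' @param profile A [profile_cluster()] result.
#' @param early_fraction Fraction of the window below which an apex counts as
#'   "early"; default 0.5.
#' @param prominence_min Minimum relative prominence for a bump; default 0.2.
#' @return One of [shape_levels()].
#' @export
classify_shape <- function(profile, early_fraction = 0.5, prominence_min = 0.2) {
  stopifnot(inherits(profile, "vm_profile"))
  L <- length(profile$mean_curve)
  if (profile$prominence >= prominence_min && profile$apex_sign != 0) {
    early <- profile$apex_index <= early_fraction * L
    if (profile$apex_sign > 0) {
      return(if (early) "early_peak" else "peak")
    }
    return(if (early) "early_trough" else "trough")
  }
  if (profile$net_change > 0) return("upslope")
  if (profile$net_change < 0) return("downslope")
  stop_validation(paste(
    "flat profile with no prominent apex cannot be classified;",
    "supply a manual override for this cluster"
  ))
}

#' Assign magnitude labels to sub-cluster profiles
#'
#' Sub-clusters are ranked by the mean absolute value of their Nm/kg mean
#' curves (ties broken by peak value, then input order) and then grouped:
#' adjacent ranks whose mean magnitudes differ by less than the `gap_ratio`
#' are treated as the same magnitude level, mirroring how a visual examiner
#' would give two indistinguishable sub-clusters the same name. Two distinct
#' levels are labelled small/large; three, small/medium/large; four, the two
#' lowest are both small (the documented convention mapping four levels onto
#' three names). Labels are invariant to uniform rescaling of all curves.
#'
#' @param profiles List of [profile_cluster()] results, one per sub-cluster,
#'   computed on Nm/kg curves.
#' @param gap_ratio Minimum ratio between adjacent mean magnitudes for them
#'   to count as different levels; default 1.5 (magnitude classes in this
#'   pipeline are expected to be at least 2x apart).
#' @return Character vector of magnitude labels in the input order.
#' @export
classify_magnitude <- function(profiles, gap_ratio = 1.5) {
  k <- length(profiles)
  if (k < 1 || k > 4) stop_validation("expected 1 to 4 sub-cluster profiles, got %d", k)
  if (k == 1) return("small")
  mean_abs <- vapply(profiles, function(p) mean(abs(p$mean_curve)), numeric(1))
  peak_abs <- vapply(profiles, function(p) max(abs(p$mean_curve)), numeric(1))
  rank_order <- order(mean_abs, peak_abs, seq_len(k))
  sorted <- mean_abs[rank_order]
  # group adjacent ranks separated by less than gap_ratio into one level
  level <- cumsum(c(1, diff(log(pmax(sorted, .Machine$double.eps))) >= log(gap_ratio)))
  n_levels <- max(level)
  labels_by_level <- switch(as.character(n_levels),
    "1" = "small",
    "2" = c("small", "large"),
    "3" = c("small", "medium", "large"),
    "4" = c("small", "small", "medium", "large")
  )
  out <- character(k)
  out[rank_order] <- labels_by_level[level]
  out
}

#' Read a manual shape-label override table
#'
#' The original cluster-to-shape assignment was a visual judgement; this
#' override path makes an analyst's relabelling first-class. The file is a
#' two-column CSV `cluster,label` mapping shape-cluster indices to labels in
#' [shape_levels()].
#'
#' @param path CSV file path.
#' @return Tibble with integer `cluster` and character `label`.
#' @export
read_shape_overrides <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  ov <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("cluster", "label") %in% names(ov))) {
    stop_format("override file needs columns 'cluster' and 'label'")
  }
  bad <- setdiff(unique(ov$label), shape_levels())
  if (length(bad) > 0) {
    stop_validation("unknown shape label(s): %s", paste(bad, collapse = ", "))
  }
  tibble(cluster = as.integer(ov$cluster), label = as.character(ov$label))
}
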