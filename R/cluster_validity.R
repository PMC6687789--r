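#' Hubert-Levin C-Index of a partition
#'
#' The C-Index compares the sum of within-cluster pairwise distances, S_w
#' over n_w pairs, with the best and worst achievable sums over the same
#' number of pairs: C = (S_w - S_min) / (S_max - S_min), where S_min and
#' S_max are the sums of the n_w smallest and largest distances among all
#' pairs. Lower is better; 0 means the within-cluster pairs are exactly the
#' globally closest pairs. The index is undefined for a single cluster, for
#' all-singleton partitions, and when all pairwise distances are equal.
#'
#' @param d A `dist` object or symmetric matrix.
#' @param labels Cluster labels aligned with the items of `d`.
#' @return The C-Index in \[0, 1\].
#' @export
c_index <- function(d, labels) {
  d <- as_distance_object(d)
  n <- attr(d, "Size")
  if (length(labels) != n) {
    stop_validation("labels length %d does not match %d items", length(labels), n)
  }
  val <- c_index_impl(as.vector(d), within_pair_mask(labels))
  if (is.na(val$c) && !is.null(val$reason)) stop_validation("%s", val$reason)
  val$c
}

# logical vector over dist-ordered pairs: TRUE where both items share a label
within_pair_mask <- function(labels) {
  m <- outer(labels, labels, "==")
  m[lower.tri(m)]
}

# core computation on the raw pair vector; returns NA with a reason when the
# index is undefined instead of erroring (the scan records these as missing)
c_index_impl <- function(dv, within, sorted = NULL, csum = NULL) {
  n_w <- sum(within)
  n_pairs <- length(dv)
  if (n_w == 0) return(list(c = NA_real_, reason = "all clusters are singletons: C-Index undefined"))
  if (n_w == n_pairs) return(list(c = NA_real_, reason = "single cluster: C-Index undefined"))
  if (is.null(sorted)) sorted <- sort(dv)
  if (is.null(csum)) csum <- cumsum(sorted)
  s_w <- sum(dv[within])
  s_min <- csum[n_w]
  s_max <- csum[n_pairs] - if (n_w == n_pairs) 0 else csum[n_pairs - n_w]
  if (s_max - s_min <= 0) {
    return(list(c = NA_real_, reason = "all pairwise distances equal: C-Index undefined"))
  }
  list(c = (s_w - s_min) / (s_max - s_min), reason = NULL)
}

#' Scan the C-Index over a range of cluster numbers
#'
#' Cuts the tree at each k in `k_min:k_max` and evaluates the C-Index of the
#' resulting partition. Values of k at which the index is undefined (e.g.
#' all-singleton cuts) are recorded as `NA`.
#'
#' @param d The `dist` object the tree was built from.
#' @param hc The [ward_linkage()] fit.
#' @param k_min,k_max Range of cluster numbers, default 2 to 50 (capped at
#'   the number of items).
#' @return A tibble of class `vm_cindex_scan` with columns `k` and `c_index`.
#' @export
c_index_scan <- function(d, hc, k_min = 2, k_max = 50) {
  d <- as_distance_object(d)
  n <- attr(d, "Size")
  k_max <- min(k_max, n)
  if (k_min > k_max) stop_validation("empty k range: %d..%d", k_min, k_max)
  if (k_min < 2) stop_validation("k_min must be at least 2")
  ks <- seq.int(k_min, k_max)
  dv <- as.vector(d)
  sorted <- sort(dv)
  csum <- cumsum(sorted)
  cuts <- stats::cutree(hc, k = ks)
  if (length(ks) == 1) cuts <- matrix(cuts, ncol = 1)
  cvals <- vapply(seq_along(ks), function(i) {
    c_index_impl(dv, within_pair_mask(cuts[, i]), sorted, csum)$c
  }, numeric(1))
  out <- tibble(k = as.integer(ks), c_index = cvals)
  class(out) <- c("vm_cindex_scan", class(out))
  out
}

#' Choose the number of clusters from a C-Index scan
#'
#' The `"threshold"` rule (the default) picks the smallest k whose C-Index is
#' at or below `threshold`; if none qualifies it falls back to the k with the
#' minimal C-Index and flags the fallback. The `"elbow"` rule picks the k
#' maximizing the discrete second difference of the C-Index curve (the first
#' such maximum; smallest k wins ties).
#'
#' @param scan A [c_index_scan()] tibble (columns `k`, `c_index`).
#' @param threshold C-Index cut-off for the threshold rule; default 0.05.
#'   Comparison is `<=`.
#' @param rule `"threshold"` or `"elbow"`.
#' @return The chosen k (integer) with attribute `"rule_used"` set to
#'   `"threshold"`, `"elbow"` or `"argmin-fallback"`.
#' @export
select_k <- function(scan, threshold = 0.05, rule = c("threshold", "elbow")) {
  rule <- match.arg(rule)
  if (nrow(scan) == 0) stop_validation("empty C-Index scan")
  ok <- !is.na(scan$c_index)
  if (!any(ok)) stop_validation("C-Index undefined at every scanned k")
  ks <- scan$k[ok]
  cs <- scan$c_index[ok]
  if (rule == "threshold") {
    hit <- which(cs <= threshold)
    if (length(hit) > 0) {
      k <- ks[hit[1]]
      attr(k, "rule_used") <- "threshold"
      return(k)
    }
    k <- ks[which.min(cs)]
    attr(k, "rule_used") <- "argmin-fallback"
    return(k)
  }
  if (length(ks) < 3) {
    k <- ks[which.min(cs)]
    attr(k, "rule_used") <- "argmin-fallback"
    return(k)
  }
  d2 <- cs[c(-1, -length(cs))] * -2 + cs[-c(1, 2)] + cs[seq_len(length(cs) - 2)]
  k <- ks[which.max(d2) + 1]
  attr(k, "rule_used") <- "elbow"
  k
}
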