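#' Two-step cluster analysis of valgus moment waveforms
#'
#' Runs the full pipeline on a long trials table. Step one (shape): trials
#' are windowed to early stance, resampled to a common length, encoded as
#' the signs of their first differences, and clustered with Ward.D2 on
#' Euclidean distances; the number of clusters is chosen from a C-Index scan
#' and each cluster is assigned one of the six shape labels from its
#' aggregate profile. Step two (magnitude): within each shape family the
#' body-mass-normalized (Nm/kg) curves are clustered the same way into 2-4
#' sub-clusters -- the sub-cluster count with the lowest C-Index wins -- and
#' sub-clusters are labelled small/medium/large by their mean absolute
#' magnitude.
#'
#' @param trials Long trials table (see [read_trials()] or
#'   [generate_cohort()]).
#' @param stance_fraction Fraction of stance analysed; default 0.30.
#' @param target_length_rule,fixed_length Common-length rule, see
#'   [common_length()].
#' @param k_range Range of cluster numbers scanned in the shape step;
#'   default 2 to 50.
#' @param c_threshold C-Index cut-off for [select_k()]; default 0.05.
#' @param select_rule `"threshold"` (default) or `"elbow"`.
#' @param sub_k_range Range of sub-cluster numbers per shape; default 2 to 4.
#' @param early_fraction,prominence_min Shape-rule parameters, see
#'   [classify_shape()].
#' @param ties Tie handling in the sign encoding, see [encode_signs()].
#' @param overrides Optional manual cluster-to-shape mapping (tibble with
#'   columns `cluster`, `label`, or a CSV path for
#'   [read_shape_overrides()]).
#' @return An object of class `vm_clustering`; see [tidy.vm_clustering()]
#'   for the per-trial labels and [glance.vm_clustering()] for the fit
#'   summary.
#' @examples
#' cfg <- generator_config(n_per_group = c(boy_1 = 30, girl_1 = 30))
#' fit <- generate_cohort(cfg, seed = 7)$trials |> cluster_moments()
#' glance(fit)
#' dplyr::count(tidy(fit), shape, magnitude)
#' @export
cluster_moments <- function(trials,
                            stance_fraction = 0.30,
                            target_length_rule = c("max_plus_2", "fixed"),
                            fixed_length = NULL,
                            k_range = c(2, 50),
                            c_threshold = 0.05,
                            select_rule = c("threshold", "elbow"),
                            sub_k_range = c(2, 4),
                            early_fraction = 0.5,
                            prominence_min = 0.2,
                            ties = c("zero", "up"),
                            overrides = NULL) {
  target_length_rule <- match.arg(target_length_rule)
  select_rule <- match.arg(select_rule)
  ties <- match.arg(ties)
  if (is.character(overrides) && length(overrides) == 1) {
    overrides <- read_shape_overrides(overrides)
  }

  curves <- preprocess_trials(trials, stance_fraction = stance_fraction,
                              target_length_rule = target_length_rule,
                              fixed_length = fixed_length)
  n <- nrow(curves)
  if (n < 4) stop_validation("need at least 4 trials to cluster, got %d", n)

  # step 1: shape clusters on the encoded waveforms
  encoded <- purrr::map(curves$curve, encode_signs, ties = ties)
  d_shape <- distance_matrix(encoded, ids = curves$trial_id)
  hc_shape <- ward_linkage(d_shape)
  scan <- c_index_scan(d_shape, hc_shape, k_min = k_range[1],
                       k_max = min(k_range[2], n - 1))
  k_shape <- select_k(scan, threshold = c_threshold, rule = select_rule)
  shape_cluster <- cut_clusters(hc_shape, k_shape)

  cluster_ids <- sort(unique(shape_cluster))
  cluster_shapes <- purrr::map_chr(cluster_ids, function(cl) {
    member <- curves$curve[shape_cluster == cl]
    ov <- if (!is.null(overrides)) overrides$label[overrides$cluster == cl]
    if (!is.null(ov) && length(ov) == 1) return(ov)
    classify_shape(profile_cluster(member),
                   early_fraction = early_fraction,
                   prominence_min = prominence_min)
  })
  names(cluster_shapes) <- cluster_ids
  shape_label <- cluster_shapes[as.character(shape_cluster)]

  # step 2: magnitude sub-clusters on Nm/kg curves, per shape family
  sub_cluster <- integer(n)
  magnitude <- character(n)
  sub_fits <- list()
  for (fam in unique(shape_label)) {
    idx <- which(shape_label == fam)
    fam_fit <- subcluster_family(curves$curve[idx], curves$trial_id[idx],
                                 sub_k_range = sub_k_range)
    sub_cluster[idx] <- fam_fit$labels
    magnitude[idx] <- fam_fit$magnitudes[fam_fit$labels]
    sub_fits[[fam]] <- fam_fit[c("scan", "k", "magnitudes")]
  }

  labels <- curves |>
    dplyr::select("trial_id", "athlete_id", "sex", "phase", "mass_kg") |>
    dplyr::mutate(
      shape_cluster = unname(shape_cluster),
      shape = unname(shape_label),
      sub_cluster = sub_cluster,
      magnitude = magnitude
    )

  structure(
    list(
      labels = labels,
      curves = curves,
      grid = attr(curves, "grid"),
      shape_hclust = hc_shape,
      shape_scan = scan,
      shape_k = as.integer(k_shape),
      shape_rule_used = attr(k_shape, "rule_used"),
      cluster_shapes = tibble(cluster = cluster_ids,
                              shape = unname(cluster_shapes)),
      sub_fits = sub_fits,
      params = list(stance_fraction = stance_fraction,
                    c_threshold = c_threshold,
                    select_rule = select_rule,
                    early_fraction = early_fraction,
                    prominence_min = prominence_min,
                    ties = ties)
    ),
    class = "vm_clustering"
  )
}

# magnitude sub-clustering of one shape family; the sub-cluster count with
# the lowest C-Index among the scanned ks wins
subcluster_family <- function(fam_curves, ids, sub_k_range = c(2, 4)) {
  n <- length(fam_curves)
  if (n < 3) {
    return(list(labels = rep(1L, n), k = 1L, scan = NULL,
                magnitudes = classify_magnitude(list(profile_cluster(fam_curves)))))
  }
  d <- distance_matrix(fam_curves, ids = ids)
  hc <- ward_linkage(d)
  k_max <- min(sub_k_range[2], n - 1)
  scan <- c_index_scan(d, hc, k_min = sub_k_range[1], k_max = k_max)
  if (all(is.na(scan$c_index))) {
    labels <- rep(1L, n)
    k <- 1L
  } else {
    k <- scan$k[which.min(scan$c_index)]
    labels <- cut_clusters(hc, k)
  }
  profiles <- purrr::map(sort(unique(labels)), function(cl) {
    profile_cluster(fam_curves[labels == cl])
  })
  list(labels = unname(labels), k = as.integer(k), scan = scan,
       magnitudes = classify_magnitude(profiles))
}

#' @describeIn cluster_moments Per-trial labels as a tibble (`trial_id`,
#'   metadata, `shape_cluster`, `shape`, `sub_cluster`, `magnitude`).
#' @param x,object A `vm_clustering` fit.
#' @param ... Unused.
#' @method tidy vm_clustering
#' @export
tidy.vm_clustering <- function(x, ...) {
  x$labels
}

#' @describeIn cluster_moments One-row fit summary: trial count, chosen
#'   cluster number and its C-Index, number of distinct shapes and
#'   magnitude sub-clusters.
#' @method glance vm_clustering
#' @export
glance.vm_clustering <- function(x, ...) {
  c_at_k <- x$shape_scan$c_index[x$shape_scan$k == x$shape_k]
  tibble(
    n_trials = nrow(x$labels),
    k_shape_clusters = x$shape_k,
    c_index = c_at_k,
    rule_used = x$shape_rule_used,
    n_shapes = dplyr::n_distinct(x$labels$shape),
    n_subclusters = sum(purrr::map_int(x$sub_fits, "k"))
  )
}

#' @export
print.vm_clustering <- function(x, ...) {
  g <- glance(x)
  cat("Two-step valgus moment waveform clustering\n")
  cat(sprintf("  %d trials, window = first %.0f%% of stance (%d points)\n",
              g$n_trials, 100 * x$params$stance_fraction, length(x$grid)))
  cat(sprintf("  shape step: %d clusters (C-Index %.3f, rule: %s) -> %d shapes\n",
              g$k_shape_clusters, g$c_index, g$rule_used, g$n_shapes))
  cat(sprintf("  magnitude step: %d sub-clusters across shapes\n", g$n_subclusters))
  counts <- dplyr::count(x$labels, .data$shape, .data$magnitude)
  cat("  labels:\n")
  for (i in seq_len(nrow(counts))) {
    cat(sprintf("    %-14s %-7s %5d\n", counts$shape[i], counts$magnitude[i],
                counts$n[i]))
  }
  invisible(x)
}

#' @describeIn chi_square_test Per-cell tibble: `row`, `col`, `observed`,
#'   `expected`, `contribution`.
#' @param x,object A `vm_chisq` object.
#' @param ... Unused.
#' @method tidy vm_chisq
#' @export
tidy.vm_chisq <- function(x, ...) {
  obs <- as.data.frame.table(x$observed, stringsAsFactors = FALSE)
  names(obs) <- c("row", "col", "observed")
  obs$expected <- as.vector(x$expected)
  obs$contribution <- as.vector(x$contributions)
  as_tibble(obs)
}

#' @describeIn chi_square_test One-row summary: `statistic`, `df`,
#'   `p_asymptotic`, `p_monte_carlo`, `n_sim`.
#' @method glance vm_chisq
#' @export
glance.vm_chisq <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df,
    p_asymptotic = x$p_asymptotic,
    p_monte_carlo = x$p_monte_carlo %||% NA_real_,
    n_sim = x$n_sim %||% NA_integer_
  )
}

#' @export
print.vm_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.4g, df = %d, asymptotic p = %.3g\n",
              x$statistic, x$df, x$p_asymptotic))
  if (!is.null(x$p_monte_carlo)) {
    cat(sprintf("Monte-Carlo p = %.4g (%s sampler, %d tables)\n",
                x$p_monte_carlo, x$sampler, x$n_sim))
  }
  min_e <- min(x$expected)
  if (min_e < 5) {
    cat(sprintf("note: smallest expected count is %.2f (< 5); prefer the Monte-Carlo p\n",
                min_e))
  }
  invisible(x)
}
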