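# Independent oracles used to cross-check the implementation.

# C-Index by explicit double loop over all pairs (Hubert-Levin definition)
oracle_c_index <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  dv <- numeric(0)
  within <- logical(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dv <- c(dv, m[i, j])
      within <- c(within, labels[i] == labels[j])
    }
  }
  n_w <- sum(within)
  s <- sort(dv)
  s_min <- sum(s[seq_len(n_w)])
  s_max <- sum(rev(s)[seq_len(n_w)])
  (sum(dv[within]) - s_min) / (s_max - s_min)
}

# Ward.D2 agglomeration by direct Lance-Williams updates on squared
# dissimilarities; returns the partition (first-appearance labels) at every k
oracle_ward_d2_partitions <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  S <- m^2
  active <- seq_len(n)
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))
  partitions <- vector("list", n)
  labels <- seq_len(n)
  partitions[[n]] <- canonical_labels(labels)
  while (length(active) > 1) {
    best_v <- Inf
    best <- c(NA, NA)
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        a <- active[j]
        b <- active[i]
        if (S[a, b] < best_v) {
          best_v <- S[a, b]
          best <- c(a, b)
        }
      }
    }
    a <- best[1]
    b <- best[2]
    for (c_ in setdiff(active, c(a, b))) {
      S[a, c_] <- S[c_, a] <-
        ((sizes[a] + sizes[c_]) * S[a, c_] + (sizes[b] + sizes[c_]) * S[b, c_] -
           sizes[c_] * S[a, b]) / (sizes[a] + sizes[b] + sizes[c_])
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
    labels[members[[a]]] <- a
    partitions[[length(active)]] <- canonical_labels(labels)
  }
  partitions
}

# relabel a partition by order of first appearance so two equivalent
# partitions compare identical
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

# exact fixed-margin p-value for a 2x2 table by full enumeration of the
# hypergeometric distribution of the top-left cell
oracle_exact_p_2x2 <- function(obs) {
  r <- rowSums(obs)
  cc <- colSums(obs)
  n <- sum(obs)
  stat <- function(a) {
    tb <- matrix(c(a, r[1] - a, cc[1] - a, n - r[1] - cc[1] + a), 2, 2)
    e <- outer(r, cc) / n
    sum((tb - e)^2 / e)
  }
  a_range <- max(0, cc[1] - r[2]):min(r[1], cc[1])
  probs <- stats::dhyper(a_range, cc[1], n - cc[1], r[1])
  stats_all <- vapply(a_range, stat, numeric(1))
  obs_stat <- stat(obs[1, 1])
  sum(probs[stats_all >= obs_stat - 1e-9])
}

# small balanced synthetic cohort used across tests
make_test_cohort <- function(n_per_group = 40, seed = 7, groups = c("boy_1", "girl_1"), ...) {
  freqs <- matrix(1 / 6, nrow = length(groups), ncol = 6,
                  dimnames = list(groups, shape_levels()))
  n <- stats::setNames(rep(n_per_group, length(groups)), groups)
  cfg <- generator_config(n_per_group = n, shape_freqs = freqs, ...)
  generate_cohort(cfg, seed = seed)
}
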