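#' Build a group-by-category contingency table
#'
#' Counts labelled trials into a rows-by-columns table. Row and column keys
#' may combine several variables (e.g. sex and phase), joined with `-`;
#' levels are ordered by first appearance in the data.
#'
#' @param data A data frame with one row per trial.
#' @param rows,cols Tidy-select of the grouping variable(s) for rows and the
#'   category variable(s) for columns.
#' @return An integer matrix with named dimnames.
#' @examples
#' tab <- ref_shape_counts() |> counts_matrix()
#' rowSums(tab)
#' @export
build_table <- function(data, rows, cols) {
  data <- as_tibble(data)
  if (nrow(data) == 0) stop_validation("no labelled trials")
  rsel <- dplyr::select(data, {{ rows }})
  csel <- dplyr::select(data, {{ cols }})
  if (ncol(rsel) == 0 || ncol(csel) == 0) {
    stop_validation("both 'rows' and 'cols' must select at least one column")
  }
  rkey <- do.call(paste, c(lapply(rsel, as.character), sep = "-"))
  ckey <- do.call(paste, c(lapply(csel, as.character), sep = "-"))
  tab <- table(factor(rkey, levels = unique(rkey)),
               factor(ckey, levels = unique(ckey)))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  names(dimnames(m)) <- c(paste(names(rsel), collapse = "-"),
                          paste(names(csel), collapse = "-"))
  m
}

#' Pearson chi-square test with per-cell contributions
#'
#' Computes expected counts from the margins (E = row total x column total /
#' N), the statistic as the sum of per-cell contributions (O - E)^2 / E with
#' no continuity correction, degrees of freedom (rows - 1)(cols - 1), and the
#' asymptotic upper-tail p-value. When `n_sim` is given, a Monte-Carlo
#' p-value is added by [monte_carlo_p()]; this is the recommended test when
#' some expected counts fall below 5, where the asymptotic reference is
#' unreliable.
#'
#' @param x Contingency table: matrix, table, or data frame of counts.
#' @param n_sim Number of Monte-Carlo tables (`NULL` to skip simulation).
#' @param seed RNG seed for the simulation (optional).
#' @param sampler Monte-Carlo sampler, see [monte_carlo_p()].
#' @param drop_empty Drop all-zero rows/columns instead of erroring.
#' @return Object of class `vm_chisq` with elements `observed`, `expected`,
#'   `contributions`, `statistic`, `df`, `p_asymptotic`, and (when simulated)
#'   `p_monte_carlo`, `n_sim`, `seed`.
#' @examples
#' tab <- counts_matrix(ref_shape_counts())
#' fit <- chi_square_test(tab)
#' round(fit$statistic, 1)
#' @export
chi_square_test <- function(x, n_sim = NULL, seed = NULL,
                            sampler = c("fixed_margins", "multinomial"),
                            drop_empty = FALSE) {
  sampler <- match.arg(sampler)
  obs <- as_count_matrix(x)
  zero_rows <- rowSums(obs) == 0
  zero_cols <- colSums(obs) == 0
  if (any(zero_rows) || any(zero_cols)) {
    if (!drop_empty) {
      stop_validation("table has all-zero row(s)/column(s); set drop_empty = TRUE to drop them")
    }
    obs <- obs[!zero_rows, !zero_cols, drop = FALSE]
  }
  if (nrow(obs) < 2 || ncol(obs) < 2) {
    stop_validation("need at least a 2 x 2 table, got %d x %d", nrow(obs), ncol(obs))
  }
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  contributions <- (obs - expected)^2 / expected
  statistic <- sum(contributions)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  out <- structure(
    list(
      observed = obs,
      expected = expected,
      contributions = contributions,
      statistic = statistic,
      df = df,
      p_asymptotic = stats::pchisq(statistic, df, lower.tail = FALSE),
      p_monte_carlo = NULL,
      n_sim = NULL,
      seed = seed,
      sampler = NULL
    ),
    class = "vm_chisq"
  )
  if (!is.null(n_sim)) {
    out$p_monte_carlo <- monte_carlo_p(obs, n_sim = n_sim, seed = seed, sampler = sampler)
    out$n_sim <- as.integer(n_sim)
    out$sampler <- sampler
  }
  out
}

#' Monte-Carlo p-value for a contingency table
#'
#' Conditional (fixed-margin) simulation: `n_sim` tables are drawn uniformly
#' from the set of tables sharing the observed row and column totals
#' (Patefield's algorithm via [stats::r2dtable()]), the chi-square statistic
#' is recomputed for each, and the p-value is estimated as
#' `(1 + #\{simulated >= observed\}) / (n_sim + 1)` -- the add-one estimator
#' that never returns zero. An unconditional `"multinomial"` sampler
#' (parametric bootstrap from the independence model) is available for
#' sensitivity analysis.
#'
#' @param x Contingency table of counts.
#' @param n_sim Number of simulated tables, at least 999; default 9999.
#' @param seed Optional RNG seed; with a fixed seed the result is
#'   reproducible.
#' @param sampler `"fixed_margins"` (default) or `"multinomial"`.
#' @return The simulated p-value, in (0, 1].
#' @examples
#' tab <- counts_matrix(ref_shape_magnitude_counts())
#' monte_carlo_p(tab, n_sim = 999, seed = 1)
#' @export
monte_carlo_p <- function(x, n_sim = 9999, seed = NULL,
                          sampler = c("fixed_margins", "multinomial")) {
  sampler <- match.arg(sampler)
  obs <- as_count_matrix(x)
  if (!is_scalar_number(n_sim) || n_sim < 999) {
    stop_validation("n_sim must be at least 999")
  }
  n_sim <- as.integer(n_sim)
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  stat_obs <- sum((obs - expected)^2 / expected)
  run <- function() {
    if (sampler == "fixed_margins") {
      tables <- simulate_margin_tables(obs, n_sim)
      # margins are fixed, so the expected counts are shared by every draw
      vapply(tables, function(tb) sum((tb - expected)^2 / expected), numeric(1))
    } else {
      p_cell <- as.vector(expected) / n
      draws <- stats::rmultinom(n_sim, size = n, prob = p_cell)
      apply(draws, 2, function(cnt) {
        tb <- matrix(cnt, nrow = nrow(obs))
        e <- outer(rowSums(tb), colSums(tb)) / n
        sum((tb[e > 0] - e[e > 0])^2 / e[e > 0])
      })
    }
  }
  stats <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  (1 + sum(stats >= stat_obs - 1e-12)) / (n_sim + 1)
}

#' Draw random contingency tables with fixed margins
#'
#' Thin wrapper over [stats::r2dtable()] (Patefield's sequential algorithm)
#' returning tables that carry the observed table's dimnames. Every draw has
#' exactly the row and column totals of `x`.
#'
#' @param x Contingency table whose margins are to be preserved.
#' @param n_sim Number of tables to draw.
#' @return List of integer matrices.
#' @export
simulate_margin_tables <- function(x, n_sim) {
  obs <- as_count_matrix(x)
  tables <- stats::r2dtable(n_sim, rowSums(obs), colSums(obs))
  lapply(tables, function(tb) {
    dimnames(tb) <- dimnames(obs)
    tb
  })
}

#' Per-row relative frequencies of a contingency table
#'
#' Each count divided by its row total, reported as a percentage. Rows with
#' a zero total get `NA` percentages and are flagged with a warning.
#'
#' @param x Contingency table of counts.
#' @return Long tibble with columns `row`, `col`, `n`, `row_total`, `pct`.
#' @examples
#' tab <- counts_matrix(ref_shape_counts())
#' frequency_report(tab) |> dplyr::filter(col == "early_peak")
#' @export
frequency_report <- function(x) {
  obs <- as_count_matrix(x)
  totals <- rowSums(obs)
  if (any(totals == 0)) {
    warn(sprintf("row(s) with zero total: %s",
                 paste(rownames(obs)[totals == 0], collapse = ", ")))
  }
  out <- as_tibble(as.data.frame.table(obs, stringsAsFactors = FALSE))
  names(out) <- c("row", "col", "n")
  out |>
    dplyr::mutate(
      row_total = totals[.data$row],
      pct = ifelse(.data$row_total > 0, 100 * .data$n / .data$row_total, NA_real_)
    )
}

as_count_matrix <- function(x) {
  if (inherits(x, "table")) x <- unclass(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_validation("expected a numeric matrix/table of counts")
  }
  if (any(is.na(x))) stop_validation("counts contain missing values")
  if (any(x < 0)) stop_validation("counts must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) stop_validation("counts must be integers")
  if (sum(x) < 1) stop_validation("grand total must be at least 1")
  storage.mode(x) <- "double"
  x
}

#' Reference contingency tables from a youth-athlete cohort
#'
#' Observed frequencies of valgus-moment waveform shapes (and, in the second
#' table, shape-by-magnitude sub-classes) by sex and maturation phase, from a
#' motion-capture cohort of 248 youth soccer and handball athletes (4797
#' change-of-direction trials). Shipped alongside the published expected
#' counts and per-cell chi-square contributions (`expected_printed`,
#' `contribution_printed`, at their original printed precision) so the test
#' implementation can be checked against them.
#'
#' @return A tibble in long format; pass through [counts_matrix()] to get the
#'   observed-count matrix.
#' @export
ref_shape_counts <- function() {
  path <- system.file("extdata", "ref_shape_counts.csv", package = "vmshapes",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccciid")
}

#' @rdname ref_shape_counts
#' @export
ref_shape_magnitude_counts <- function() {
  path <- system.file("extdata", "ref_shape_magnitude_counts.csv",
                      package = "vmshapes", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "cccciid")
}

#' Observed-count matrix of a long reference table
#'
#' @param counts A tibble from [ref_shape_counts()] or
#'   [ref_shape_magnitude_counts()].
#' @return Integer matrix of observed counts, groups (sex-phase) in rows.
#' @export
counts_matrix <- function(counts) {
  if ("magnitude" %in% names(counts)) {
    counts <- dplyr::mutate(counts, category = paste(.data$shape, .data$magnitude, sep = "-"))
  } else {
    counts <- dplyr::mutate(counts, category = .data$shape)
  }
  counts <- dplyr::mutate(counts, group = paste(.data$sex, .data$phase, sep = "-"))
  out <- tidyr::pivot_wider(counts[c("group", "category", "observed")],
                            names_from = "category", values_from = "observed",
                            values_fill = 0L)
  m <- as.matrix(out[-1])
  rownames(m) <- out$group
  names(dimnames(m)) <- c("group", "category")
  m
}
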