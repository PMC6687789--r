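#' Read stance-phase moment trials from a long CSV
#'
#' Reads per-trial joint-moment time series from the canonical long (tidy)
#' format: one row per recorded frame with the columns `trial_id`,
#' `athlete_id`, `sex`, `phase`, `mass_kg`, `frame` and `value_nm`. Frames
#' must form a contiguous 0-based run within each trial and body mass must be
#' positive. Extra metadata columns are accepted and carried through
#' untouched.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble with one row per frame, ordered by `trial_id` then
#'   `frame`, validated by [validate_trials()].
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(generator_config(n_per_group = c(boy_1 = 3)), seed = 1)
#' write_trials(cohort$trials, path)
#' trials <- read_trials(path)
#' dplyr::count(trials, trial_id)
#' @seealso [write_trials()], [cluster_moments()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("trial_id", "athlete_id", "sex", "phase", "mass_kg", "frame", "value_nm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_format("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  raw <- dplyr::mutate(
    raw,
    trial_id = as.character(.data$trial_id),
    athlete_id = as.character(.data$athlete_id),
    sex = as.character(.data$sex),
    phase = as.character(.data$phase),
    mass_kg = as.numeric(.data$mass_kg),
    frame = as.integer(.data$frame),
    value_nm = as.numeric(.data$value_nm)
  )
  trials <- dplyr::arrange(raw, .data$trial_id, .data$frame)
  validate_trials(trials)
}

#' Validate a long trials table
#'
#' Checks the invariants the rest of the pipeline relies on: required columns
#' present, no missing values in them, positive body mass, at least 4 frames
#' per trial, and frames forming a contiguous 0-based run (which also rules
#' out duplicated `(trial_id, frame)` rows). Malformed trials are reported by
#' id.
#'
#' @param trials A data frame in the long trial format (see [read_trials()]).
#' @return The validated table as a tibble, invisibly usable in a pipe.
#' @export
validate_trials <- function(trials) {
  trials <- as_tibble(trials)
  required <- c("trial_id", "athlete_id", "sex", "phase", "mass_kg", "frame", "value_nm")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop_format("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    if (anyNA(trials[[col]])) {
      bad <- which(is.na(trials[[col]]))
      stop_validation("column '%s' has missing values (e.g. row %d)", col, bad[1])
    }
  }
  bad_mass <- unique(trials$trial_id[trials$mass_kg <= 0])
  if (length(bad_mass) > 0) {
    stop_validation("non-positive body mass for trial(s): %s",
                    paste(utils::head(bad_mass, 5), collapse = ", "))
  }
  by_trial <- split(trials$frame, trials$trial_id)
  for (id in names(by_trial)) {
    fr <- by_trial[[id]]
    if (anyDuplicated(fr)) {
      dup <- fr[duplicated(fr)][1]
      stop_validation("duplicate frame %d in trial '%s'", dup, id)
    }
    if (!identical(as.integer(sort(fr)), seq(0L, length(fr) - 1L))) {
      stop_validation("frames of trial '%s' are not a contiguous 0-based run", id)
    }
    if (length(fr) < 4) {
      stop_validation("trial '%s' has %d frames; at least 4 are required", id, length(fr))
    }
  }
  meta <- dplyr::distinct(trials, .data$trial_id, .data$mass_kg)
  if (anyDuplicated(meta$trial_id)) {
    stop_validation("trial '%s' has inconsistent mass_kg across rows",
                    meta$trial_id[duplicated(meta$trial_id)][1])
  }
  trials
}

#' Write trials to the canonical long CSV
#'
#' @param trials A validated long trials table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Write per-trial shape/magnitude labels to CSV
#'
#' One record per trial: `trial_id`, `shape`, `magnitude`, `shape_cluster`,
#' `sub_cluster`. Fields containing the delimiter are quoted so the file
#' round-trips exactly through [read_results()].
#'
#' @param results A data frame of labelled trials, e.g. `tidy()` of a
#'   [cluster_moments()] fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as_tibble(results)
  if (nrow(results) == 0) stop_validation("no labelled trials to write")
  required <- c("trial_id", "shape", "magnitude", "shape_cluster", "sub_cluster")
  missing_cols <- setdiff(required, names(results))
  if (length(missing_cols) > 0) {
    stop_format("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  readr::write_csv(results[required], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    trial_id = readr::col_character(),
                    shape = readr::col_character(),
                    magnitude = readr::col_character(),
                    shape_cluster = readr::col_integer(),
                    sub_cluster = readr::col_integer()
                  ))
}

#' Export a clustering fit as machine-readable JSON
#'
#' Writes the audit trail of a [cluster_moments()] fit: the shape-step merge
#' list with heights, the C-Index scans of both steps, the chosen cluster
#' numbers, and the per-trial labels.
#'
#' @param fit A `vm_clustering` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clustering_json <- function(fit, path) {
  stopifnot(inherits(fit, "vm_clustering"))
  payload <- list(
    n_trials = nrow(fit$labels),
    shape_step = list(
      linkage = linkage_tibble(fit$shape_hclust),
      c_index_scan = fit$shape_scan,
      k = fit$shape_k,
      rule_used = fit$shape_rule_used
    ),
    magnitude_step = purrr::map(fit$sub_fits, function(sf) {
      list(c_index_scan = sf$scan, k = sf$k)
    }),
    labels = fit$labels
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
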