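#' Window a series to the early stance phase
#'
#' Keeps the first `ceiling(stance_fraction * length(x))` samples. The default
#' 0.30 captures early weight acceptance -- the interval in which ACL injuries
#' occur -- with enough margin to show slopes on either side of an early peak.
#' The ceiling rule means the window never undershoots the requested fraction.
#'
#' @param x Numeric vector of moment samples covering the stance phase.
#' @param stance_fraction Fraction of stance to keep, in (0, 1].
#' @return The windowed numeric vector (at least 3 samples).
#' @export
window_series <- function(x, stance_fraction = 0.30) {
  if (!is_scalar_number(stance_fraction) || stance_fraction <= 0 || stance_fraction > 1) {
    stop_validation("stance_fraction must be in (0, 1], got %s", format(stance_fraction))
  }
  n <- ceiling(stance_fraction * length(x))
  if (n < 3) {
    stop_validation("window of %d samples is too short (minimum 3)", n)
  }
  x[seq_len(n)]
}

#' Common resampling length for a set of windowed series
#'
#' Under the default `"max_plus_2"` rule the target length is the longest
#' series plus two frames; `"fixed"` uses `fixed_length` regardless of input.
#'
#' @param lengths Integer vector of series lengths (or a list of series).
#' @param rule `"max_plus_2"` or `"fixed"`.
#' @param fixed_length Target length when `rule = "fixed"`.
#' @return A single positive integer.
#' @export
common_length <- function(lengths, rule = c("max_plus_2", "fixed"), fixed_length = NULL) {
  rule <- match.arg(rule)
  if (is.list(lengths)) lengths <- lengths(lengths)
  if (length(lengths) == 0) stop_validation("no series supplied")
  if (rule == "fixed") {
    if (!is_scalar_number(fixed_length) || fixed_length < 2) {
      stop_validation("fixed_length must be an integer >= 2")
    }
    return(as.integer(fixed_length))
  }
  as.integer(max(lengths) + 2L)
}

#' Resample a series by piecewise-linear interpolation
#'
#' Interpolates onto `target_length` equally spaced positions spanning the
#' original first and last samples; endpoints are preserved exactly and
#' resampling a series to its own length is the identity. Linear (rather than
#' spline) interpolation is used so that no overshoot can introduce spurious
#' direction changes into the sign encoding.
#'
#' @param x Numeric vector, length >= 2.
#' @param target_length Number of output samples, >= 2.
#' @return Numeric vector of length `target_length`.
#' @export
resample_series <- function(x, target_length) {
  if (length(x) < 2) stop_validation("series must have at least 2 samples")
  if (!is_scalar_number(target_length) || target_length < 2) {
    stop_validation("target_length must be >= 2")
  }
  target_length <- as.integer(target_length)
  if (target_length == length(x)) return(x)
  stats::approx(x = seq_along(x), y = x, n = target_length)$y
}

#' Normalize a moment series by body mass
#'
#' Elementwise division, turning Nm into Nm/kg. Moments are scaled by body
#' mass because ACL tensile strength scales with body size, making Nm/kg the
#' comparable loading unit across athletes.
#'
#' @param x Numeric vector in Nm.
#' @param mass_kg Body mass in kilograms, > 0.
#' @return Numeric vector in Nm/kg.
#' @export
normalize_by_mass <- function(x, mass_kg) {
  if (!is_scalar_number(mass_kg) || mass_kg <= 0) {
    stop_validation("mass_kg must be a positive number")
  }
  x / mass_kg
}

#' Window, resample and normalize a cohort of trials
#'
#' Runs the preprocessing chain on a long trials table: each trial is windowed
#' to early stance, the common target length is computed over the windowed
#' series (longest + 2 by default), every series is linearly resampled to that
#' length, and curves are divided by body mass. Windowing precedes resampling
#' by default; `window_first = FALSE` resamples the full stance first and
#' windows afterwards, exposed for sensitivity analysis.
#'
#' @param trials Long trials table (see [read_trials()]).
#' @param stance_fraction Fraction of stance analysed; default 0.30.
#' @param target_length_rule `"max_plus_2"` or `"fixed"`.
#' @param fixed_length Target length when the rule is `"fixed"`.
#' @param window_first If `TRUE` (default) window then resample.
#' @return A tibble with one row per trial: the trial metadata, `n_frames`
#'   (raw length), and list-columns `curve_nm` (resampled window, Nm) and
#'   `curve` (the same in Nm/kg). The common grid of stance-fraction
#'   positions is attached as attribute `"grid"`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_per_group = c(boy_1 = 5)), seed = 1)
#' curves <- preprocess_trials(cohort$trials)
#' lengths(curves$curve)
#' @export
preprocess_trials <- function(trials, stance_fraction = 0.30,
                              target_length_rule = c("max_plus_2", "fixed"),
                              fixed_length = NULL, window_first = TRUE) {
  trials <- validate_trials(trials)
  target_length_rule <- match.arg(target_length_rule)
  nested <- trials |>
    dplyr::group_by(.data$trial_id, .data$athlete_id, .data$sex, .data$phase, .data$mass_kg) |>
    dplyr::summarise(values = list(.data$value_nm[order(.data$frame)]), .groups = "drop") |>
    dplyr::arrange(match(.data$trial_id, unique(trials$trial_id)))

  if (window_first) {
    windowed <- purrr::map(nested$values, window_series, stance_fraction = stance_fraction)
    len <- common_length(lengths(windowed), rule = target_length_rule,
                         fixed_length = fixed_length)
    curves <- purrr::map(windowed, resample_series, target_length = len)
  } else {
    len_full <- common_length(lengths(nested$values), rule = target_length_rule,
                              fixed_length = fixed_length)
    resampled <- purrr::map(nested$values, resample_series, target_length = len_full)
    curves <- purrr::map(resampled, window_series, stance_fraction = stance_fraction)
    len <- length(curves[[1]])
  }

  out <- nested |>
    dplyr::mutate(
      n_frames = lengths(.data$values),
      curve_nm = curves,
      curve = purrr::map2(curves, .data$mass_kg, normalize_by_mass)
    ) |>
    dplyr::select(-"values")
  attr(out, "grid") <- seq(0, stance_fraction, length.out = len)
  attr(out, "stance_fraction") <- stance_fraction
  out
}

#' Stack a list-column of equal-length curves into a matrix
#'
#' @param curves List of equal-length numeric vectors (e.g. the `curve`
#'   column of [preprocess_trials()]), optionally named.
#' @param ids Row names; defaults to names of `curves`.
#' @return A numeric matrix, one curve per row.
#' @export
curve_matrix <- function(curves, ids = NULL) {
  len <- unique(lengths(curves))
  if (length(len) != 1) {
    stop_validation("curves have unequal lengths: %s", paste(len, collapse = ", "))
  }
  m <- do.call(rbind, curves)
  rownames(m) <- ids %||% names(curves)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
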