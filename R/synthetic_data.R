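#' Templates for the six synthetic waveform families
#'
#' Unit-amplitude stance-phase templates emulating the six qualitative
#' valgus-moment shapes. Peak/trough families are asymmetric Gaussian bumps
#' (negative for troughs): the side facing the nearer window edge is steep
#' (width 0.04-0.05 of stance) and the side spanning the rest of the window
#' decays slowly (width 0.085), so the moment rises and falls with a
#' physiologically sustained slope across the whole analysis window. The
#' monotone families are logistic ramps centred mid-window; their `gain` of
#' 2.5 reflects that monotone curves keep loading beyond the window and so
#' reach larger within-window excursions than a bump of the same class. The
#' early bump apex (0.10 of stance, one third of the default window) falls
#' inside the "early" half of the window; the late apex (0.21, seven tenths
#' of the window) beyond it. No biomechanical fidelity is claimed beyond
#' these qualitative features.
#'
#' @return A tibble with columns `shape`, `kind`, `center`, `rise_width`,
#'   `fall_width`, `gain`, `sign` (positions/widths in stance fractions).
#' @export
shape_templates <- function() {
  tibble(
    shape = shape_levels(),
    kind = c("bump", "bump", "ramp", "ramp", "bump", "bump"),
    center = c(0.10, 0.21, 0.15, 0.15, 0.21, 0.10),
    rise_width = c(0.05, 0.085, 0.05, 0.05, 0.085, 0.05),
    fall_width = c(0.085, 0.04, 0.05, 0.05, 0.04, 0.085),
    gain = c(1, 1, 2.5, 2.5, 1, 1),
    sign = c(1, 1, 1, -1, -1, -1)
  )
}

# evaluate a unit-amplitude template at stance fractions t in [0, 1]
template_curve <- function(shape, t) {
  tmpl <- shape_templates()
  row <- tmpl[tmpl$shape == shape, ]
  if (nrow(row) != 1) stop_validation("unknown shape family '%s'", shape)
  base <- if (row$kind == "bump") {
    w <- ifelse(t < row$center, row$rise_width, row$fall_width)
    exp(-0.5 * ((t - row$center) / w)^2)
  } else {
    stats::plogis((t - row$center) / row$rise_width)
  }
  row$sign * row$gain * base
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the reference cohort: per-group
#' trial counts of 1512 (phase-1 boys), 2502 (phase-1 girls), 364 (phase-2
#' boys) and 419 (phase-2 girls); per-group shape frequencies taken from the
#' reference shape table's row proportions; bump/ramp amplitudes of 0.3
#' Nm/kg for the small class with 2x/4x multipliers for medium/large; smooth
#' additive noise (moving-average-filtered white noise, sd 0.03 Nm/kg = 10
#' percent of the small amplitude, correlation length 5 frames); a slow
#' per-trial baseline component (sd 0.05 Nm/kg, correlation length 25
#' frames) emulating idiosyncratic postural offsets that do not scale with
#' moment magnitude; raw series lengths uniform on 90-110 frames; and
#' per-group body-mass distributions matching the cohort descriptives
#' (means 40.2/41.8/74.9/64.0 kg).
#'
#' @param n_per_group Named integer vector of trial counts; names are
#'   `sex_phase` keys such as `boy_1`. Defaults to the study counts.
#' @param shape_freqs Matrix of shape frequencies (groups x shapes), rows
#'   summing to 1. Defaults to the reference table row proportions.
#' @param magnitude_probs Named list mapping each shape to a named
#'   probability vector over magnitude classes.
#' @param base_amplitude Small-class amplitude in Nm/kg.
#' @param magnitude_multipliers Named multipliers for small/medium/large.
#' @param noise_sd Standard deviation of the additive smooth noise, Nm/kg.
#' @param noise_span Correlation length (frames) of the smoothed noise.
#' @param trend_sd Standard deviation of the slow per-trial baseline
#'   component, Nm/kg (0 disables it).
#' @param trend_span Correlation length (frames) of the baseline component.
#' @param length_range Integer range of raw series lengths.
#' @param mass_mean,mass_sd Named per-group body-mass parameters (kg).
#' @return A list of class `vm_generator_config`.
#' @export
generator_config <- function(n_per_group = NULL,
                             shape_freqs = NULL,
                             magnitude_probs = NULL,
                             base_amplitude = 0.3,
                             magnitude_multipliers = c(small = 1, medium = 2, large = 4),
                             noise_sd = 0.03,
                             noise_span = 5,
                             trend_sd = 0.05,
                             trend_span = 25,
                             length_range = c(90L, 110L),
                             mass_mean = c(boy_1 = 40.2, girl_1 = 41.8,
                                           boy_2 = 74.9, girl_2 = 64.0),
                             mass_sd = c(boy_1 = 8.1, girl_1 = 9.4,
                                         boy_2 = 16.5, girl_2 = 10.3)) {
  if (is.null(n_per_group)) {
    n_per_group <- c(boy_1 = 1512L, girl_1 = 2502L, boy_2 = 364L, girl_2 = 419L)
  }
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    stop_validation("n_per_group must be a named vector of 'sex_phase' keys")
  }
  if (any(n_per_group < 0)) stop_validation("trial counts must be non-negative")
  if (is.null(shape_freqs)) {
    ref <- ref_shape_counts()
    wide <- counts_matrix(ref)
    rownames(wide) <- sub("-", "_", rownames(wide))
    shape_freqs <- wide / rowSums(wide)
  }
  missing_groups <- setdiff(names(n_per_group), rownames(shape_freqs))
  if (length(missing_groups) > 0) {
    stop_validation("no shape frequencies for group(s): %s",
                    paste(missing_groups, collapse = ", "))
  }
  if (any(abs(rowSums(shape_freqs) - 1) > 1e-6)) {
    stop_validation("shape frequency rows must sum to 1")
  }
  if (is.null(magnitude_probs)) {
    two <- c(small = 0.6, large = 0.4)
    three <- c(small = 0.65, medium = 0.28, large = 0.07)  # mirrors observed trough proportions
    magnitude_probs <- list(
      early_peak = two, peak = two, upslope = two, downslope = two,
      trough = three, early_trough = three
    )
  }
  for (grp in setdiff(names(n_per_group), names(mass_mean))) {
    mass_mean[grp] <- 45
    mass_sd[grp] <- 10
  }
  structure(
    list(
      n_per_group = n_per_group,
      shape_freqs = shape_freqs,
      magnitude_probs = magnitude_probs,
      base_amplitude = base_amplitude,
      magnitude_multipliers = magnitude_multipliers,
      noise_sd = noise_sd,
      noise_span = as.integer(noise_span),
      trend_sd = trend_sd,
      trend_span = as.integer(trend_span),
      length_range = as.integer(length_range),
      mass_mean = mass_mean,
      mass_sd = mass_sd
    ),
    class = "vm_generator_config"
  )
}

# moving-average-filtered white noise, rescaled to sd; autocorrelated so
# that differencing does not produce pure sign chatter
smooth_noise <- function(n, sd, span) {
  if (sd == 0) return(numeric(n))
  z <- stats::rnorm(n + span - 1)
  cs <- c(0, cumsum(z))
  ma <- (cs[(span + 1):(n + span)] - cs[seq_len(n)]) / span
  sd * sqrt(span) * ma
}

#' Generate one synthetic stance-phase trial
#'
#' Evaluates the family template on a stance grid of `n_frames` samples,
#' scales it by the magnitude class amplitude, adds smooth noise and the
#' slow per-trial baseline component, and converts Nm/kg to Nm with the
#' athlete's body mass. Uses the current RNG
#' state; seed control lives in [generate_cohort()].
#'
#' @param shape One of [shape_levels()].
#' @param magnitude One of [magnitude_levels()].
#' @param config A [generator_config()].
#' @param n_frames Raw series length; drawn from `length_range` if `NULL`.
#' @param mass_kg Body mass; drawn from the first group's mass distribution
#'   if `NULL`.
#' @return A list with `values` (Nm, length `n_frames`), `values_nm_kg`,
#'   `mass_kg`, `n_frames`, `shape`, `magnitude`.
#' @export
generate_trial <- function(shape, magnitude, config = generator_config(),
                           n_frames = NULL, mass_kg = NULL) {
  shape <- match.arg(shape, shape_levels())
  magnitude <- match.arg(magnitude, magnitude_levels())
  if (is.null(n_frames)) {
    n_frames <- sample(seq(config$length_range[1], config$length_range[2]), 1)
  }
  if (is.null(mass_kg)) {
    mass_kg <- max(20, stats::rnorm(1, config$mass_mean[[1]], config$mass_sd[[1]]))
  }
  t <- seq(0, 1, length.out = n_frames)
  amplitude <- config$base_amplitude * config$magnitude_multipliers[[magnitude]]
  nm_kg <- amplitude * template_curve(shape, t) +
    smooth_noise(n_frames, config$noise_sd, config$noise_span) +
    smooth_noise(n_frames, config$trend_sd, config$trend_span)
  list(values = nm_kg * mass_kg, values_nm_kg = nm_kg, mass_kg = mass_kg,
       n_frames = n_frames, shape = shape, magnitude = magnitude)
}

#' Generate a labelled synthetic cohort
#'
#' Draws, for each group, the configured number of trials with shapes sampled
#' from the group's frequency vector and magnitude classes from the
#' per-shape class probabilities. Trials are grouped into athletes of at
#' most 20 trials each; body mass is drawn once per athlete from the group's
#' distribution. Output is reproducible: the same seed yields identical
#' cohorts.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `vm_cohort`: `trials` (long tibble in the
#'   [read_trials()] format) and `truth` (one row per trial with the
#'   generating `shape` and `magnitude`).
#' @examples
#' cohort <- generate_cohort(generator_config(n_per_group = c(boy_1 = 10)), seed = 42)
#' dplyr::count(cohort$truth, shape)
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "vm_generator_config"))
  withr::with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  trial_rows <- list()
  truth_rows <- list()
  trial_no <- 0L
  for (grp in names(config$n_per_group)) {
    n <- config$n_per_group[[grp]]
    if (n == 0) next
    parts <- strsplit(grp, "_", fixed = TRUE)[[1]]
    sex <- parts[1]
    phase <- parts[2]
    freqs <- config$shape_freqs[grp, ]
    shapes <- sample(colnames(config$shape_freqs), n, replace = TRUE, prob = freqs)
    athlete_idx <- ceiling(seq_len(n) / 20)
    masses <- vapply(seq_len(max(athlete_idx)), function(i) {
      max(20, stats::rnorm(1, config$mass_mean[[grp]], config$mass_sd[[grp]]))
    }, numeric(1))
    for (i in seq_len(n)) {
      trial_no <- trial_no + 1L
      probs <- config$magnitude_probs[[shapes[i]]]
      magnitude <- sample(names(probs), 1, prob = probs)
      tr <- generate_trial(shapes[i], magnitude, config,
                           mass_kg = masses[athlete_idx[i]])
      id <- sprintf("t%05d", trial_no)
      trial_rows[[trial_no]] <- tibble(
        trial_id = id,
        athlete_id = sprintf("%s_a%03d", grp, athlete_idx[i]),
        sex = sex, phase = phase,
        mass_kg = tr$mass_kg,
        frame = seq(0L, tr$n_frames - 1L),
        value_nm = tr$values
      )
      truth_rows[[trial_no]] <- tibble(
        trial_id = id, sex = sex, phase = phase,
        shape = tr$shape, magnitude = tr$magnitude, mass_kg = tr$mass_kg
      )
    }
  }
  structure(
    list(trials = dplyr::bind_rows(trial_rows), truth = dplyr::bind_rows(truth_rows)),
    class = "vm_cohort"
  )
}
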