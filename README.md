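# vmshapes

Two-step cluster analysis of knee valgus moment (VM) waveforms for
sports-injury biomechanics.

## The problem

The external knee valgus moment during a cutting maneuver loads the ACL,
and ACL ruptures occur within ~50 ms of ground contact. Conventional
analyses reduce each trial's VM time series to a single peak value, but VM
waveforms are heterogeneous — some peak early (inside the injury window),
some late, some rise or fall monotonically — so the extracted peak is often
unrelated to injury timing. `vmshapes` implements a classification-first
alternative for researchers analysing joint-moment time series:

1. **Shape step.** Each trial's curve, windowed to the first 30% of stance
   and resampled to a common length, is reduced to the signs of its first
   differences, $s_k = \mathrm{sign}(x_{k+1}-x_k)$ — a ternary encoding
   that keeps direction changes and discards magnitude. Encoded curves are
   clustered with Ward.D2 on Euclidean distances; the number of clusters
   is the smallest $k \in \{2,\dots,50\}$ whose Hubert–Levin C-Index
   $C = (S_w - S_{\min})/(S_{\max} - S_{\min})$ drops to 0.05, and each
   cluster is labelled `early_peak`, `peak`, `upslope`, `downslope`,
   `trough` or `early_trough` from its aggregate profile.
2. **Magnitude step.** Within each shape, body-mass-normalized (Nm/kg)
   curves are sub-clustered (2–4 sub-clusters, lowest C-Index wins) and
   the sub-clusters labelled `small` / `medium` / `large` by mean absolute
   magnitude.
3. **Frequency analysis.** Group × category label counts are tested with
   Pearson chi-square (expected counts, per-cell contributions
   $(O-E)^2/E$, asymptotic p) and a fixed-margin Monte-Carlo significance
   test for sparse tables.

A seeded synthetic waveform generator with ground-truth labels makes the
whole pipeline testable without motion-capture data.

## Worked example

```r
library(vmshapes)

# a labelled synthetic cohort: 2 groups x 120 trials, six waveform families
freqs <- matrix(1/6, 2, 6, dimnames = list(c("boy_1", "girl_1"), shape_levels()))
cfg <- generator_config(n_per_group = c(boy_1 = 120, girl_1 = 120), shape_freqs = freqs)
cohort <- generate_cohort(cfg, seed = 42)

fit <- cohort$trials |> cluster_moments()
fit
#> Two-step valgus moment waveform clustering
#>   240 trials, window = first 30% of stance (35 points)
#>   shape step: 6 clusters (C-Index 0.030, rule: threshold) -> 6 shapes
#>   magnitude step: 15 sub-clusters across shapes
#>   labels:
#>     downslope      large      12
#>     downslope      small      18
#>     early_peak     large      24
#>     early_peak     small      21
#>     ...
```

The C-Index scan crossed the 0.05 cut-off at k = 6 clusters (C = 0.030),
which classify into all six shape families; the magnitude step then split
them into 15 sub-clusters. `tidy(fit)` returns one labelled row per trial,
`glance(fit)` the one-row fit summary, `autoplot(fit)` the mean curve per
shape/magnitude class, and `write_clustering_json()` a full audit trail
(merge heights, C-Index scans, labels).

Frequency analysis against the packaged reference table of 4797 trials
from a youth-athlete cohort:

```r
tab <- counts_matrix(ref_shape_counts())   # 4 groups x 6 shapes
chi_square_test(tab, n_sim = 9999, seed = 1)
#> Pearson chi-square: X^2 = 400.1, df = 15, asymptotic p = 6.59e-76
#> Monte-Carlo p = 0.0001 (fixed_margins sampler, 9999 tables)

frequency_report(tab) |> dplyr::filter(col == "early_peak")
#> # A tibble: 4 x 5
#>   row    col            n row_total   pct
#> 1 boy-1  early_peak   575      1512  38.0
#> 2 girl-1 early_peak   642      2502  25.7
#> 3 boy-2  early_peak    78       364  21.4
#> 4 girl-2 early_peak   178       419  42.5
```

The statistic of 400.1 on 15 df says the shape distribution differs
strongly by sex and phase; the early-peak percentages show the reversal
that matters clinically — pre-adolescent boys show more early peaks than
girls (38% vs 26%), adolescent girls more than boys (42% vs 21%),
mirroring the 2–3× higher ACL injury rate of adult female athletes.

Command-line wrappers over the same functions live in `inst/scripts/`
(`simulate.R`, `cluster.R`, `freqtest.R`).

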