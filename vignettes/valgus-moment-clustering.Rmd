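---
title: "Two-step cluster analysis of knee valgus moment waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step cluster analysis of knee valgus moment waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmshapes)
library(dplyr)
```

## The problem

The external knee valgus moment (VM) during the stance phase of a cutting
maneuver loads the anterior cruciate ligament, and ACL ruptures happen in
the first ~50 ms after ground contact. Summarising a VM time series by its
global peak therefore often extracts a value that has nothing to do with
the injury window: some athletes' curves peak early, some late, some rise
or fall monotonically through early stance. Rather than force a single
summary statistic onto heterogeneous waveforms, the approach implemented
here first asks *what shape* each trial's early-stance VM curve has, and
only then *how large* it is, via two rounds of hierarchical clustering.
Group differences (e.g. by sex and maturation phase) in the frequency of
each shape/magnitude class are then tested with chi-square statistics.

## The two-step procedure

**Step 0 — preprocessing.** Each trial's moment series is windowed to the
first 30% of stance (`stance_fraction = 0.30`, ceiling rule so the window
never undershoots), linearly resampled to a common length equal to the
longest window plus two frames, and divided by body mass to give Nm/kg.
Linear rather than spline interpolation is used deliberately: splines can
overshoot and would manufacture direction changes that the next step would
treat as signal. Windowing precedes resampling; the opposite order is
available (`window_first = FALSE`) for sensitivity analysis.

**Step 1 — shape.** Each curve of length $L$ is reduced to the signs of its
lagged differences: $s_k = \mathrm{sign}(x_{k+1} - x_k) \in \{-1, 0, +1\}$,
$k = 1, \dots, L-1$. This encoding discards all magnitude information — it
is invariant to positive scaling and offsets, and antisymmetric under
negation — leaving only the waveform's direction changes. Euclidean
distances between encoded curves feed Ward.D2 agglomerative clustering
(minimum-variance criterion in the Murtagh–Legendre formulation: the
Lance–Williams update runs on squared dissimilarities and merge heights are
reported on the original scale). The number of clusters is chosen by
scanning the Hubert–Levin C-Index

$$C = \frac{S_w - S_{\min}}{S_{\max} - S_{\min}},$$

where $S_w$ is the sum of within-cluster pairwise distances over $n_w$
pairs and $S_{\min}, S_{\max}$ are the sums of the $n_w$ smallest/largest
distances overall, for $k = 2, \dots, 50$; the smallest $k$ with
$C \le 0.05$ wins (comparison is `<=`, so a scan touching exactly 0.05 is
accepted). When no $k$ crosses the threshold the scan falls back to the
$k$ minimising $C$ and records `rule_used = "argmin-fallback"`. An elbow
rule (maximum discrete second difference of the C-Index curve, smallest
$k$ on ties) is available; the threshold rule is the default because on
smooth C-Index curves an "elbow" is ill-defined.

Each resulting cluster is assigned one of six semantic labels from its
aggregate profile — the pointwise mean curve, its apex (the interior point
deviating most from the chord joining the endpoints), the apex's sign and
timing, and its prominence (apex deviation relative to the curve's range):

* prominent positive apex (prominence ≥ 0.2): `early_peak` if the apex
  falls in the first half of the window (i.e. 15% of stance), else `peak`;
* prominent negative apex: `early_trough` / `trough` by the same timing rule;
* otherwise a monotone slope: `upslope` or `downslope` by the sign of the
  net change; an exactly flat profile is refused and requires a manual
  override.

The 0.5-window ("early") boundary brackets the empirical observation that
early peaks fall within the first quarter of stance while keeping the rule
symmetric for troughs; the 0.2 prominence floor separates bump shapes from
monotone slopes with a wide margin on the generator families (noiseless
bumps profile at ~0.95, logistic ramps at ~0.11). Both are arguments of
`classify_shape()`. Because the original assignment of clusters to shapes
was done by eye, a manual override table (`cluster,label` CSV) always takes
precedence when supplied.

**Step 2 — magnitude.** Within each shape family the *Nm/kg* curves (not
the encodings) are clustered the same way, scanning 2–4 sub-clusters and
keeping the count with the lowest C-Index. Sub-clusters are ranked by the
mean absolute value of their mean curves and labelled small / medium /
large. Two refinements matter here:

* *Gap-aware labelling.* Adjacent ranks whose mean magnitudes differ by
  less than 1.5× share a label. When sub-clustering happens to split one
  homogeneous magnitude level into two, forcing distinct names onto
  indistinguishable sub-clusters would be wrong — a visual examiner would
  call both "small". Classes that genuinely differ (the pipeline expects
  ≥ 2× spacing) are unaffected.
* *Four sub-clusters map onto three names* by labelling the two lowest
  ranks small.

## The frequency analysis

`build_table()` counts labelled trials into a groups × categories matrix
(levels ordered by first appearance). `chi_square_test()` computes expected
counts from the margins, the uncorrected Pearson statistic
$\sum (O-E)^2/E$ with its per-cell contributions (no Yates correction — the
published contribution values are reproducible only without it), the
asymptotic upper-tail p, and, on request, a Monte-Carlo p: `n_sim` tables
drawn uniformly from the set with the observed margins fixed (Patefield's
algorithm via `stats::r2dtable`), the statistic recomputed for each, and

$$\hat p = \frac{1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\}}{n_{sim} + 1},$$

the add-one estimator that never returns zero. The conditional test is the
appropriate choice when expected counts drop below 5, which is exactly the
situation in the shape-by-magnitude table; an unconditional multinomial
sampler is available behind `sampler = "multinomial"` for sensitivity
analysis. Because the margins are fixed, the expected counts are shared by
every draw, which keeps 9999 simulations on a 4×14 table well under a
second.

`frequency_report()` returns exact per-row percentages. When comparing
against the published integer percentages, note that those integers are
reproduced by *truncation* toward zero, not rounding: one group's
early-peak share is 25.66%, printed as 25%. The package reports full
precision and leaves display rounding to the caller.

## The synthetic cohort generator

No raw waveforms are distributable, so `generate_cohort()` provides a fully
labelled stand-in emulating the study conditions: per-group trial counts of
1512/2502/364/419 (sex × phase), per-group shape frequencies equal to the
reference table's row proportions, at most 20 trials per athlete with body
mass drawn once per athlete from the group's descriptive distribution, and
raw series lengths uniform on 90–110 frames (~0.3–0.5 s of stance at
typical motion-capture rates).

Each trial is `amplitude × template + smooth noise + slow baseline`:

* **Templates.** Bump families are asymmetric Gaussians — the side facing
  the nearer window edge is steep (width 0.04–0.05 of stance) and the other
  side decays slowly (0.085) — centred at 0.10 (early) and 0.21 (late) of
  stance; monotone families are logistic ramps centred at 0.15 with width
  0.05 and a 2.5× template gain, reflecting that monotone curves keep
  loading beyond the window and so reach larger within-window excursions.
  These choices make the *slope* of every template exceed the noise
  increment over most of the window, which is what "well-separated in
  encoded space" means for a differencing encoder: separation lives in the
  signs of slopes, not in curve values.
* **Magnitude classes.** Small/medium/large multiply a 0.3 Nm/kg base
  amplitude by 1/2/4. Bump families default to two classes (60/40),
  trough families to three (65/28/7), mirroring the reference table.
* **Smooth noise.** Moving-average-filtered white noise, sd 0.03 Nm/kg
  (10% of the small amplitude) with a 5-frame correlation length. White
  noise would be wrong here: a differencing encoder turns uncorrelated
  noise into pure sign chatter.
* **Slow baseline.** An amplitude-*independent* smooth component (sd 0.05
  Nm/kg, 25-frame correlation length) emulating idiosyncratic postural
  offsets. Besides realism, this term has a methodological role: it gives
  every family internal spread, which keeps the C-Index above the 0.05
  threshold for k below the family count so the scan resolves all six
  families, and—because it does not scale with amplitude—it leaves the
  magnitude classes equally tight.

What the generator does **not** emulate: musculoskeletal coupling, ground
reaction forces, autocorrelated athlete-level strategies across trials, or
the continuous (classless) magnitude distribution of real cohorts. Passing
recovery tests on these cohorts therefore demonstrates that the pipeline is
implemented correctly and behaves as designed under known structure — not
that it would recover any particular structure in new laboratory data.

## Validation and problem sizes

The test-suite checks (all in code, none precomputed):

* C-Index against a brute-force all-pairs oracle on random 10-point
  instances, and Ward.D2 partitions against an independent Lance–Williams
  implementation at every k on random 8-point configurations;
* the published 4×6 frequency table: statistic 400.1, all 24 expected
  counts and contributions at printed precision, and the group-wise
  early-peak percentages;
* the Monte-Carlo test against exact enumeration on 2×2 fixed-margin
  problems and against the asymptotic p on well-populated tables;
* end-to-end recovery on cohorts of 300 trials (six families × 50, the
  smallest size the recovery claim is stated for): median adjusted Rand
  index of the shape labels and median magnitude-class accuracy over three
  generated cohorts must reach 0.9. The median over three cohorts (rather
  than one draw) is the test's operationalisation of "recovers under the
  stated regime": a single 300-trial draw leaves a few percent sampling
  variance around the 0.9 line.

These sizes keep the whole suite under a minute while exercising every
code path; the pipeline itself handles study-sized cohorts (≈4800 trials)
in well under an hour, with the distance matrix the dominant cost.

## Known limitations

* **Tie-breaking in Ward.D2** follows `stats::hclust`'s internal order.
  On continuous dissimilarities ties are a measure-zero event, but encoded
  waveforms tie frequently (identical curves at distance zero), so
  permuting the input can relabel or reshape tied merges. Order stability
  is guaranteed only for tie-free inputs.
* **Three magnitude levels and the lowest-C-Index rule interact badly**
  when classes are geometrically spaced (each level ≥ 2× the one below):
  the large class is then farther from medium than medium is from small,
  so at two sub-clusters the pairs excluded from the within-cluster sum
  are exactly the largest ones and the C-Index is structurally ~0. The
  rule prefers isolating the large class and merges small with medium.
  The resulting errors are always merges, never inversions — a medium
  trial may be called small, but never large — and overall magnitude
  accuracy stays above 90% in the recovery tests. Analysts wanting three
  levels should inspect the sub-cluster scan and override.
* **The shape taxonomy is a rule, not ground truth.** The quantitative
  `classify_shape()` rules replace a visual judgement; borderline clusters
  (apex near the early/late boundary, prominence near 0.2) can flip
  labels. The override path exists precisely because the original
  assignment admitted inter-rater disagreement.
* **The C-Index threshold of 0.05 is a convention**, not an inferential
  quantity; there is no consensus on selecting cluster numbers this way,
  and on data whose C-Index curve hovers near the threshold the selected
  k is sensitive to sampling noise.
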