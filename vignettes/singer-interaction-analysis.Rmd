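---
title: "Quantifying countersinging interactions between humpback whale singers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying countersinging interactions between humpback whale singers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songdyad)
```

## The problem

Male humpback whales sing long, hierarchically structured songs: units form
phrases, a phrase type is repeated several times (a *theme*), and themes are
cycled in a broadly shared order for hours at a time. Song is continuous
(pauses between phrases are no longer than pauses between notes), all males
in a population draw on essentially the same phrase repertoire, and singers
use *eventual variety* — repeating a type before switching. These four
properties defeat the standard songbird toolkit for detecting acoustic
interaction (song-type matching, overlap timing), because some coincidence
between two singers' songs is expected even when they ignore each other.

`songdyad` implements an analysis pipeline for the resulting study design:
a *focal* singer sings alone for an up-to-45-min **BEFORE** period, a
*second* singer starts (the *onset*), and both are followed for an
up-to-45-min **DURING** period. Three song-pattern measures and two
movement measures quantify whether the focal singer responded.

## Song-pattern measures

### Analysis windows

Each period is subdivided into 15-min windows (`segment_windows()`):
DURING windows tile forward from the onset, BEFORE windows tile backward.
Males typically cycle through their full repertoire within about 15 min,
so a window captures a representative stretch of song while retaining
temporal resolution. Real BEFORE periods are often shorter than 45 min; a
leading partial window is kept only when it is at least 2/3 of the window
length (600 s by default), so that per-window metrics stay comparable.
A phrase belongs to the window containing its midpoint — unambiguous and
symmetric at boundaries. Transitions are counted within windows only; the
per-window metric is then averaged over the period, so a switch falling
exactly on a window boundary contributes to neither window.

### Switching rate

For a window containing `Pn` phrases with `Tn` transitions between
different phrase types,

    SR = Tn / (Pn - 1),

in [0, 1]. Windows with fewer than two phrases leave SR undefined; such
windows are recorded but excluded from the period mean.

### Relative song evenness

The normalized Shannon entropy of phrase-type proportions,

    J' = -sum_i p_i log(p_i) / log(k),

where `p_i` is the proportion of the window's phrases of type `i` and `k`
is the singer's repertoire size. `J' = 1` means all `k` types equally
represented; `J' = 0` means a single type. The log base cancels; we use
natural logs. Because population song changes across seasons, `k` must
reflect the repertoire *at the time of recording*: we take the union of
types the singer produced over his analyzed span (BEFORE + DURING for the
focal singer, DURING for the second; `repertoire_of()`). A per-window `k`
would conflate evenness with window length; a fixed population-wide `k`
would penalize singers for types not currently in the song.

### Phrase-type overlap and the Monte Carlo time-shift null

Both singers' phrase types are sampled every 8 s on a grid anchored at the
onset (`sample_phrase_grid()`); the statistic is the proportion of
co-sampled grid points (both singers audible) at which the two types are
equal (`overlap_proportion()`). A proportion is used rather than a raw
count because time-shifted replicate sequences cover the grid unevenly,
and because a proportion is comparable across dyads with different
surfacing-gap structure.

The null distribution (`mc_overlap_test()`) restarts the second singer's
*entire* sequence — phrase order, durations and internal gaps preserved —
at a start time drawn uniformly within the BEFORE period, and re-measures
the overlap on the same grid; 1000 replicates by default. This preserves
everything cyclical and repetitive about both songs and randomizes only
their relative timing, which is exactly the coincidence structure the test
must control for. P-values use the add-one convention,
`p = (1 + #{null >= observed}) / (1 + reps)`, so a finite simulation never
reports zero. Both tails are reported: a small left-tail p indicates
matching *avoidance*, which is biologically meaningful.

Two guards deal with shifts that barely reach the DURING window: a
replicate with fewer than 25% of the grid co-sampled is redrawn (up to 10
times, then recorded as missing and excluded, with the count reported).
And at the pipeline level a dyad is excluded from the matching analysis
altogether when either singer covered less than half of the DURING period.
The second rule matters: with a short second-singer sequence the
coverage guard concentrates all admissible start times into a narrow band
next to the true onset, so the null explores only a sliver of relative
cycle phases, becomes far too narrow, and the test rejects spuriously. We
observed exactly this on synthetic uncoupled dyads with a second singer
quitting at ~44% of DURING. The operation itself stays general — callers
who want the raw test on short coverage can still run it — but
`run_study()` and the analysis drivers apply the exclusion.

## Movement measures

Tracks are time-stamped planar positions (meters in a local projection,
e.g. from the center of a hydrophone array), linearly interpolated where a
position between fixes is needed. Separation statistics
(`dyad_spatial()`) are the distances between the two singers at the start
and end of the DURING window, and their difference (negative = approach).
If a track misses a window endpoint — surfacings and excursions out of an
array degrade localization — the nearest covered time within 300 s stands
in; larger gaps are an error rather than a silent guess.

The meander ratio (`meander_ratio()`) is path length over chord length,
with the path summed over positions at sequential 5-min bin boundaries:
1 for straight travel, much greater than 1 for milling. The 5-min binning
deliberately undersamples the track; summing every 2.5-min fix would
accumulate localization jitter (tens of meters per fix) into spurious path
length. When the chord is under 1 m — far below localization error — the
ratio is reported as undefined rather than as an arbitrarily large number.

The spatial null (`solo_pairwise_null()`) superimposes the tracks of solo
singers recorded at non-overlapping times, as though they had sung
simultaneously: since they could not have interacted, their pairwise
separations are random with respect to one another. All `choose(n, 2)`
pairs of `n` solo singers contribute (18 singers give 153 pairs). Observed
dyad distributions are compared to the null with two-sample K-S tests;
the change-in-distance-by-outcome comparison (did one singer quit?) uses a
Mann-Whitney U; meander comparisons use a Wilcoxon signed-rank (focal
BEFORE vs DURING) and a Mann-Whitney U (focal vs second, DURING).
Proportions (SR, J') are arcsine-square-root transformed
(`asin(sqrt(p))`, the standard variance stabilizer for proportions)
before their paired t-tests. With study sizes of ~9-11 dyads, exact
small-sample p-values are used wherever ties permit.

## The synthetic-data generator

No recordings are deposited for this kind of study, so the package ships
generators that emulate the statistical structure the analysis assumes,
making every stage testable end to end.

* **Song** (`simulate_song()`): eventual-variety Markov sequences over a
  repertoire of 10 phrase types (the most present in a population-wide
  song at one time). The singer repeats the current type and switches with
  per-phrase probability `switch_prob`, cyclically through the repertoire;
  repetition counts are geometric and the expected switching rate *equals*
  `switch_prob`, giving a clean parameter-recovery target. The default
  `switch_prob = 0.15` sits in the range realized by wild singers
  (roughly 0.1-0.15). Phrase durations are truncated-normal, 15 ± 4 s with
  a 3-s floor, so ~45-min periods contain on the order of 150-240 phrases;
  occasional 20-s surfacing gaps interrupt the sequence.
* **Coupling** (`simulate_dyad()`): at each of his phrase starts, the
  second singer adopts the focal's concurrent phrase type with probability
  `coupling_m` — he finishes his current phrase first, as an
  eventual-variety singer must. `coupling_m = 0` gives independent songs
  (the null the overlap test should not reject); `coupling_m = 1` forces
  near-total matching.
* **Tracks** (`simulate_track()`): correlated random walks at 1 m/s
  sampled every 60 s; `turn_sd_rad = 0` gives straight travel (meander
  exactly 1), large values give milling, and an optional attraction point
  produces directed approach. A quit rule truncates a singer's annotations
  at the first sub-threshold separation, emulating song cessation on close
  approach.
* **Solo population** (`simulate_solo_population()`): independent tracks
  with start positions scattered over a 6 km x 3 km footprint, the
  coverage of a nearshore hydrophone array.

What the generator does **not** emulate: cultural song change within a
season, individual repertoire differences, localization error on
positions, intermittent detection dropouts beyond simple gaps, or any
dependence of movement on song content. Passing tests therefore
demonstrate that the *methods* are correct and calibrated under the
stated model — not that real singers behave like the model.

## Numerical and design choices

* Times are seconds from the recording start, stored to millisecond
  precision (array channels are synchronized to about ±1 ms); files
  round-trip exactly at that precision.
* Same-singer overlapping phrase annotations are an input error, never
  auto-repaired: song is a non-overlapping phrase sequence, so overlap
  indicates an annotation mistake.
* Monte Carlo results are bit-reproducible given the scenario seed; every
  generator is deterministic under its seed.
* Undefined metrics (SR with < 2 phrases, J' with k < 2, meander with a
  sub-threshold chord, overlap with no co-samples) are signalled as `NA`
  or a typed condition and excluded from averages and tests — never
  silently zeroed.
* Degenerate statistical inputs (zero-variance differences, all-tied
  samples) raise a typed condition that `run_study()` converts into an
  `NA` row, so a report is still produced.

## Problem sizes used by the test suite

The calibration test runs 20 independent synthetic dyads at 200 Monte
Carlo replicates each, for both `coupling_m = 0` (size: rejections at
alpha = 0.05 must fall inside the 95% binomial band) and
`coupling_m = 0.9` (power: at least 80% rejections); parameter recovery
uses 50 seeds. These sizes give stable pass/fail behavior while keeping
the full suite under a minute on one CPU; the shipped analysis scripts run
the full 1000-replicate version.

## Limitations

* The time-shift null assumes the second singer's sequence is long enough
  for shifts to decorrelate cycle phase (hence the 50%-coverage exclusion).
* Acoustic localization is out of scope: tracks are inputs, and the
  pipeline inherits whatever error they carry.
* Linear interpolation stands in for the specialized track-interpolation
  tooling used with acoustic arrays; over 2.5-5-min gaps at ~1 m/s the
  difference is small relative to localization error.
* No multiple-testing correction is applied across the report's tests, as
  is conventional in these small exploratory study designs; with ~10
  tests per study, isolated p-values near 0.05 should be read accordingly.

## A minimal session

```{r, eval = FALSE}
sc <- dyad_scenario("F", "S", onset_s = 2700, seed = 1)
sim <- simulate_dyad(dyad_gen_params(coupling_m = 0.9), sc)

w <- segment_windows(sc)
period_metrics(sim$annotations, "F", w,
               repertoire_of(sim$annotations, "F"), "DURING")

mc_overlap_test(sim$annotations, sim$annotations, sc)

solo <- simulate_solo_population(18, seed = 1)
nrow(solo_pairwise_null(solo))  # 153
```
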