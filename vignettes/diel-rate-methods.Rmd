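---
title: "Methods: exposure-adjusted diel analysis of record rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-adjusted diel analysis of record rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielrate)
```

## The model

The unit of analysis is the *scheduled round*: a (competition, event, round
number) triple with a UTC start time, an attempt count (its exposure) and a
pooled count of record-setting performances (its outcome). Record
probability at local time *t* is estimated as records per attempt among
rounds *starting* in the 15-minute bin containing *t*. This is an
exposure-adjusted rate: because competitions concentrate rounds at
particular hours, raw record counts by clock time mix scheduling density
with any genuine diel performance variation, and dividing by per-bin
attempts removes the scheduling component.

Three modelling assumptions matter:

1. **Round start time stands for solve time.** All of a round's attempts are
   assigned the round's start bin. Rounds last tens of minutes, so the
   effective temporal resolution is coarser than the bin width; a true
   effect confined to a narrow window is diluted by rounds that start before
   it and run into it.
2. **Local civil clock time proxies diel phase.** No chronotype, travel or
   solar-time correction is attempted.
3. **Records are pre-flagged outcomes.** The analysis consumes record flags
   as given and pools WR/CR/NR tiers and single/average categories; the
   elite-gated lineage process that produces them is outside the model.

## Inference: the within-competition permutation null

Conditioning on the observed schedule is essential: the question is not
"are records uniform over the day" (they cannot be — exposure is not) but
"given where exposure sat, are records distributed over it uniformly". The
null therefore reallocates each stratum's total record count across that
stratum's rounds with multinomial probabilities proportional to attempt
counts. Attempts are never moved, so the exposure curve is identical in
every draw, and per-stratum record totals are conserved exactly.

The stratum is the (competition, event) group. A stratum restricted to a
single round — the literal per-round reading — is degenerate: all of a
round's attempts share one start bin, so reallocation cannot move records
between bins and every null draw equals the observed statistic. The package
exposes this reading (`stratum = "competition_event_round"`) purely to
demonstrate the degeneracy; a test asserts that it yields p = 1.

Two statistics are available:

* `max_deviation`: `T = max_b |r_b − r̄| / r̄` over *valid* bins (those
  meeting the minimum-attempts filter), with `r̄` recomputed per permuted
  table. `T` is scale-invariant and targets any departure from uniformity.
* `window_ratio`: the outside/inside pooled-rate ratio for a clock window,
  by default the post-prandial window 12:30–15:00 (the early-afternoon
  interval in which a transient alertness reduction tied to the 12-hour
  harmonic of the circadian system is expected). Values above 1 indicate
  suppression inside the window.

Both are tested one-tailed in the upper tail with the add-one estimator
`p = (1 + #{null ≥ observed}) / (1 + B)`, which is valid for permutation
tests and never reports p = 0. Ties count toward the tail, making the test
conservative when record counts are small and the ratio's support is coarse.

Two deliberately different bin sets coexist: the display/validity filter
(`min_attempts`, per event) governs which bins enter the rate figure and the
`T` statistic, while the outside-window rate pools *all* bins with at least
one attempt. Observed and null statistics always use identical bin sets,
fixed from the observed table. One numerical subtlety: the observed window
statistic is computed inside the test with the same arithmetic expression as
the null draws (record and attempt counts only, no display scale), so that
exact ties are exact in floating point rather than differing in the last
bit.

## Parameters and defaults

| parameter | default | units / meaning |
|---|---|---|
| bin width | 15 min | must divide 60; bins are half-open `[start, start+width)` |
| window | 12:30–15:00 | end-exclusive; boundaries must sit on bin edges |
| scales | 333: 100,000; 444: 50,000; 555: 20,000; 666: 5,000 | display denominator (records per N attempts) |
| min_attempts | 333: 10,000; 444: 7,825; 555: 3,954; 666: 977 | per-bin validity threshold, treated as fixed constants of the analysis convention |
| iterations | 10,000 | permutation draws |
| seed | 42 | RNG seed; identical inputs and seed give bit-identical null draws |
| era boundary | 2023 | era strata are pre-2023 (≤ 2022) vs 2023+ by competition year |
| evening search window | 17:00–19:00 | where `final_round_share()` looks for the raw peak bin |

The min-attempts defaults assume real-export exposure volumes; on synthetic
data of desk scale they would invalidate every bin, so analysis functions
take explicit overrides (`min_attempts =`). `r̄` is the *unweighted* mean of
valid-bin rates (reading "mean rate across valid bins" literally); the
attempt-weighted alternative — which equals the pooled rate over valid bins
— is available via `rate_mean = "weighted"`.

A boundary convention worth stating: a round starting exactly at 15:00 is
*outside* the 12:30–15:00 window (half-open intervals throughout), and bin
identity is by local civil clock only — the civil date is dropped after
timezone conversion, pooling rounds across dates and daylight-saving
regimes.

## Ingestion conventions and degenerate inputs

* Results tables may be per-solve (record-flag columns for the single and
  average categories) or pre-aggregated per round; both normalise to pooled
  per-round tier tallies. Every started solve counts as one attempt, DNFs
  included — the permissive reading, configurable in principle by supplying
  pre-aggregated counts. A solve setting both a single and an average record
  contributes two pooled records by default
  (`count_both_categories = FALSE` collapses it to one).
* Schedules are a documented JSON subset: venues with IANA timezones, rooms,
  activities with `"<event>-r<k>"` codes and UTC start timestamps. The same
  round listed in several rooms takes the earliest start. A document with no
  venue/activity records excludes its competition with reason
  `"no schedule"`; a missing file is `"no file"`; unreadable JSON or a
  malformed timestamp is `"parse failure"`. The coverage summary (retained /
  queried) is computed over retained plus excluded competitions.
* Unknown timezones are a hard error — no geographic imputation exists.
* Round stages come from the *full* contested sequence (validated contiguous
  from 1) before any schedule-driven drop: the highest round is the final,
  rounds 1–2 that are not the final are "early", later non-final rounds are
  "other" — an explicit third stratum rather than a silent merge, so the
  early and final strata need not exhaust an event's records.
* Zero-attempt rounds are retained as exposure-zero; bins with zero attempts
  have undefined rates and are never valid. A stratum with records but zero
  inside-window attempts is *untestable* and flagged as such; a stratum with
  inside exposure but zero inside records has an unbounded suppression
  estimate and reports `NA` for the ratio while keeping its rates.

The exact Poisson interval (Garwood, via chi-square quantiles; lower bound
exactly 0 at zero records) is used instead of a normal approximation because
per-bin record counts are small. The unit tests check it against an
independent oracle that inverts the cumulative Poisson distribution by
root-finding.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes: competitions with continent-consistent timezones; per-event round
sequences whose local start bins follow a scheduling-density curve (default:
a heavy 08:00–11:00 morning block, a lighter 11:00–17:00 plateau, and a
17:00–19:00 evening block); finals redirected into the evening block with
probability 0.7, modelling the compositional confound that final rounds
cluster late; log-normal attempt counts shrinking geometrically across
rounds; and records drawn as `Binomial(attempts, p_eff)` with an optional
multiplicative dip inside a configurable window. Defaults were chosen once
as a realistic emulation: 200 competitions, continent mix 0.40/0.25/0.25/
0.06/0.04 (Europe/Asia/Americas/Oceania/Africa), years 2012–2025 (the
electronic-scheduling era), per-event baseline probabilities placed so
pooled rates land near each event's display convention (e.g. ~30 per 50,000
for 444), and cosmetic NR/CR/WR tier proportions 0.94/0.05/0.01.

What the generator deliberately does **not** emulate: the elite-gated record
process (each real record must beat all prior ones, creating temporal
thinning and era structure), competitor-level skill and selection into
finals, within-round solve timing, and venue-level idiosyncrasies. Passing
tests therefore certify the *pipeline* — binning, exposure adjustment, null
construction, calibration, recovery of a known generative dip — not any
claim about real competition data.

UTC timestamps are synthesised by anchoring rounds at local bin starts on a
random date and converting through the venue timezone; the stored bin is
then *recomputed from the UTC time* exactly as ingestion would, so fixture
round-trips agree even across daylight-saving transitions (a nonexistent
local time at a spring-forward gap is shifted forward one hour).

## Test design and problem sizes

The suite favours property checks over point examples: bins partition the
day; window and complement partition the bins; tallies conserve attempts and
records; the attempt-weighted mean rate equals the pooled rate as an exact
identity; raising the validity threshold never adds valid bins; permutation
draws conserve records per stratum in every iteration and never touch
exposure; identical seeds give identical draws.

Three checks are sized by design rather than convenience, with sizes chosen
a priori from power and feasibility calculations:

* **Size calibration**: 200 flat-rate replicates (400 competitions each, one
  event, first-round attempts log-normal around 400) × 500 permutations;
  the rejection rate at α = 0.05 must land in [0.02, 0.08]. The replicate
  size guarantees the inside-window record count is essentially never zero,
  which would abort the observed statistic; the discreteness of the ratio's
  support makes the test mildly conservative, which the band anticipates.
* **Enumeration oracle**: a one-stratum, two-round, two-record instance
  where the null has three multinomial outcomes with known probabilities;
  the estimated p must match the enumerated tail probability within twice
  its Monte-Carlo standard error at 10,000 iterations.
* **Dip recovery**: 2,000 competitions (>10⁶ attempts) with a 0.8 dip
  multiplier; the estimated outside/inside ratio must fall within three
  delta-method standard errors of 1/0.8 = 1.25.

The raw-versus-adjusted contrast — record counts tracking the scheduling
density (correlation > 0.9) while adjusted rates carry no such imprint — is
checked with the finals' evening redirection disabled, since the invariant's
premise is that start bins follow the density curve itself; with
redirection enabled the raw curve tracks realized exposure instead, which is
the same phenomenon seen through a different curve.

## Known limitations

* Power at desk scale is modest: with a few hundred records the window
  ratio's null distribution is wide and discrete, and single-round strata
  contribute no information to the within-competition null (their records
  cannot move). Non-rejection is never evidence of absence.
* The generator's independent-Bernoulli records ignore record lineage; any
  analysis of record *sequences* is out of scope.
* No smoothing or harmonic (cosinor) fit of the rate curve is provided; the
  statistics operate on raw binned rates.
* No multiple-testing correction is applied across events or statistics;
  p-values are per-event and one-tailed by construction.
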