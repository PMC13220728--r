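# dielrate

Exposure-adjusted time-of-day analysis of record rates in competition data.

## The problem

Record-setting performances at scheduled competitions (the motivating case is
speedcubing under World Cube Association rules, with WR/CR/NR records across
puzzle events) cluster at particular clock times. That clustering confounds
two mechanisms: competitions schedule far more rounds at some hours than
others, and performance itself may vary over the day — for instance a
post-prandial alertness dip in the early afternoon (12:30–15:00). `dielrate`
is for analysts who want to separate the two using only observational
schedule and results data.

## The method

Each scheduled round contributes its attempt count as *exposure* and its
pooled record count as *outcome*, at the round's local start time (UTC start
converted through the venue's IANA timezone, discretised into 96
quarter-hour bins). The exposure-adjusted record probability in bin *t* is

```
P(record | t) = records in rounds starting in bin t / attempts in rounds starting in bin t
```

displayed as records per *N* attempts with per-event scales (333: 100,000;
444: 50,000; 555: 20,000; 666: 5,000), exact (Garwood) Poisson 95% intervals,
and a per-event minimum-attempts validity filter (10,000 / 7,825 / 3,954 /
977).

Two statistics are evaluated against a **within-competition permutation
null**: each competition-event's total record count is reallocated across its
own rounds by a multinomial draw proportional to attempts, preserving
schedule and exposure structure exactly.

* non-uniformity: `T = max_b |r_b − r̄| / r̄` over valid bins;
* post-prandial contrast: the outside/inside window rate ratio, where the
  outside rate pools all bins with ≥ 1 attempt outside 12:30–15:00.

One-tailed p-values use the add-one estimator `(1 + #{null ≥ obs}) / (1 + B)`.
Sensitivity analyses recompute the window ratio within continent, era
(pre-2023 vs 2023+) and round-stage strata, and the evening peak's
final-round record share quantifies the compositional explanation of the raw
evening spike. A seedable synthetic generator emulates the whole data layer
(bimodal scheduling density, evening-biased finals, optional multiplicative
dip) so every stage is testable without any external download.

## Worked example

```r
library(dielrate)

cfg <- synthetic_config(
  n_competitions = 800,
  events = list("444" = list(rounds_dist = c(0.45, 0.35, 0.20, 0),
                             attempts_meanlog = log(400), attempts_sdlog = 0.4,
                             baseline_p = 6e-4)),
  dip_multiplier = 0.7,   # 30% suppression of record probability in 12:30-15:00
  seed = 2026)
ds <- generate_dataset(cfg)
ds
#> <diel_dataset> 800 competitions, 1411 rounds, 0 excluded
#>   444: 476952 attempts, 298 records
#>   schedule coverage: 800/800 competitions (100.0%)

tab <- tally_bins(ds, "444", min_attempts = 1000)
wr  <- window_rates(tab, window_spec())      # 12:30-15:00 default
round(c(wr$inside_rate, wr$outside_rate), 2)
#> [1] 23.49 32.00                             # records per 50,000 attempts
run_permutation_test(ds, "444", iterations = 10000, seed = 2026)
#> <perm_test> window_ratio, event 444
#>   observed = 1.3624, one-tailed p = 0.1239 (10000 iterations, seed 2026)
run_permutation_test(ds, "444", statistic = "max_deviation",
                     iterations = 10000, seed = 2026, min_attempts = 1000)
#> <perm_test> max_deviation, event 444
#>   observed = 1.9935, one-tailed p = 0.006399 (10000 iterations, seed 2026)

dip_ratio_by(ds, "444", "round_stage")
#>   grouping    label n_records inside_rate outside_rate dip_ratio testable
#> 1 round_stage early       132        23.6         28.6      1.21 TRUE
#> 2 round_stage final       166        23.1         35.0      1.51 TRUE
final_round_share(ds, "444")$final_share
#> [1] 0.889                                   # evening peak is finals-driven
```

The generated 30% dip surfaces as an outside/inside ratio of 1.36 (true
value 1/0.7 ≈ 1.43); at ~300 records the window test has limited power
(p = 0.12), while the non-uniformity statistic rejects (p = 0.006). The
round-stage table and the 88.9% final-round share at the 17:00 peak bin show
the evening elevation in raw counts coming from finals scheduling, not
performance.

Real data enter through the same path via `read_results_table()`,
`read_schedules()`, `read_competitions()` and `join_dataset()` (or
`read_fixtures()` for a directory in the bundled dialects), and
`run_analysis()` writes a full report directory (rate tables, test JSONs,
sensitivity CSVs, composition summaries, config echo). A thin CLI wrapper
lives at `inst/scripts/dielrate.R` (`simulate` / `analyze` subcommands).

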