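# runcontingent

Discovery and classification of **spawning-run contingents** — run-timing
groups within one spawning population — from river acoustic-telemetry
detection logs, with run-timing statistics and contingent-specific survival
analysis.

Anadromous fish such as striped bass can split a spring spawning run into
contingents that target different river reaches on different schedules, and
those groups can then meet very different mortality (for example, the
early-departing group reaching coastal fisheries first). This package turns a
raw detection log into that full analysis, and ships a synthetic telemetry
generator with ground-truth labels so the whole pipeline can be exercised and
validated without field data.

## The method

Per fish and year, detections are reduced to a daily river-kilometre
phenology: the mean position of each detected day, interior gaps filled by a
two-sided exponential-weighted moving average (window 4 d, weights
2<sup>−d</sup>), the run anchored between its outermost crossings of the
entry/exit threshold (river km 43), and all runs of a cohort-year padded to a
common date axis with the constant river km 35 so that timing differences
remain visible to the distance measure.

The core fit is `contingent_cluster()`: k-medoids (deterministic multi-start
PAM) under a **dynamic time warping** dissimilarity

> DTW(a, b) = min over monotone warping paths of the cumulative cost, local
> cost |a<sub>i</sub> − b<sub>j</sub>|, `symmetric2` step weighting,

which matches run phenologies that are alike in shape, extent, and
destination even when offset in time — exactly where lockstep (Euclidean)
matching fails. Each cluster's centroid is its medoid phenology; with k = 2
clusters are labelled `upper`/`lower` by centroid peak. `predict()` classifies
a later year's tracks onto the fitted centroids on a day-of-year axis, and
`cross_classify()` tests cross-year persistence (concordance + chi-square).

Attrition per contingent uses the last-detection-as-loss design:
instantaneous daily loss rates *Z* (OLS slope of log extant counts),
Kaplan–Meier curves with Greenwood standard errors, and the Peto & Peto
modified Gehan–Wilcoxon (weighted log-rank) test between contingents.

## Worked example

```r
library(runcontingent)

sim <- simulate_runs(synthetic_config(), years = c(2017, 2018), seed = 42)
rep <- run_pipeline(sim$detections, sim$receivers, sim$fish, sim$environment)
print(rep)
#> Contingent analysis report
#>   years: 2017, 2018
#> DTW k-medoids contingent model (k = 2, symmetric2, L1)
#>   60 series, total within-cluster cost 1.584e+04
#>   cluster 1 ('lower'): 30 series, medoid 'F016', peak km 98.0
#>   cluster 2 ('upper'): 30 series, medoid 'F052', peak km 183.0
#> Cross-year classification of 32 fish
#>        year2
#> year1   lower upper
#>   lower    10     1
#>   upper     3    18
#> Concordance: 88%  (chi-square = 14.5, df = 1, p = 0.000137)
#> Between-contingent survival tests:
#>  year         groups   weights statistic df    p_value
#>  2017 lower vs upper peto-peto 5.3863949  1 0.02029436
#>  2018 lower vs upper peto-peto 0.7225086  1 0.39532228
```

Reading this: the 60 simulated first-year phenologies split cleanly into a
lower-reach cluster (peak ~km 98) and an upper-reach cluster (~km 183); of
the fish that returned and were classified in both years, 88% kept their
contingent (the generator's true fidelity is 0.89); and post-run survival
differed between contingents in 2017 (Peto–Peto p = 0.02) but not 2018 —
the generator's hazards are contingent-specific, so this is the expected
recovery. Timing statistics per contingent-year:

```r
rep$tables$phenology[, c("contingent", "year", "n_fish", "median_entry",
                         "median_exit", "date_50pct", "temp_50pct_C")]
#>  contingent year n_fish median_entry median_exit date_50pct temp_50pct_C
#>       lower 2017     30   2017-04-17  2017-05-19 2017-04-17     6.812891
#>       upper 2017     30   2017-04-23  2017-06-07 2017-04-23     9.109878
#>       lower 2018     13   2018-04-14  2018-05-16 2018-04-14     6.027117
#>       upper 2018     19   2018-04-26  2018-06-12 2018-04-26    10.624246
```

`write_report(rep, "outdir")` writes all tables (`series.csv`,
`assignments.csv`, `crossclass.csv`, `phenology.csv`, `survival.csv`,
`km_curves.csv`, `tests.csv`, `fish_status.csv`) as schema-versioned CSVs
plus a run log. A thin CLI over the same functions lives at
`inst/cli/runcontingent.R` (`simulate` / `analyze` subcommands), and
pipeline constants (thresholds, window, k, censoring) are settable from YAML
via `read_config()`.

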