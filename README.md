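# conformalqc

Conformal-prediction quality control for diagnostic classifiers that output
class probabilities — written with AI-assisted prostate biopsy grading
(benign vs cancer, ISUP grade groups 1–5) in mind, but applicable to any
probabilistic classifier.

A deployed AI system produces a probability vector per example and, on its
own, no statement of reliability. `conformalqc` wraps those outputs in a
**Mondrian inductive conformal predictor**: a held-out calibration set
provides, per true class *k*, the nonconformity scores
α<sub>i</sub> = 1 − p̂<sub>y<sub>i</sub></sub>(x<sub>i</sub>), and a new
example's candidate label *k* receives the p-value

> p<sub>k</sub>(x) = ( #{ i : α<sub>i</sub> ≥ α\*} + 1 ) / (n<sub>k</sub> + 1),  α\* = 1 − p̂<sub>k</sub>(x)

(a smoothed, tie-randomized variant is also provided). The **prediction
region** is every label with p<sub>k</sub> > 1 − c(k) at the chosen
(possibly class-wise) confidence c. Under exchangeability the true label is
excluded with probability at most 1 − c(k), *within each class*. Regions of
size ≠ 1 (empty or multiple) flag unreliable predictions for human review;
violations of the validity guarantee flag dataset shift — a new scanner, a
different laboratory, atypical tissue.

The package covers the full quality-control loop:

| step | functions |
|---|---|
| synthetic score generation, shift scenarios | `simulate_scores()`, `apply_shift()` |
| splitting & calibration | `split_train_calibration()`, `mondrian_calibrate()` |
| p-values & regions | `conformal_pvalue()`, `predict_regions()` |
| evaluation | `tally_regions()`, `point_prediction_tally()`, `calibration_curve()`, `panel_coverage()`, `region_size_stats()`, `human_in_loop_auc()` |
| drift & power | `drift_test()`, `power_curve()` |
| orchestration & I/O | `run_pipeline()`, `read_score_table()`, CSV/JSON/YAML helpers, `inst/scripts/conformalqc-cli.R` |

## Worked example

Simulate a grading cohort with a screening-trial class mix, calibrate, form
class-wise-confidence regions on a fresh test set, and probe a distorted
deployment set:

```r
library(conformalqc)
labels <- isup_labels()
mix <- c(3724, 1530, 539, 263, 469, 426)   # raw class counts, normalized internally

cohort <- simulate_scores(
  synthetic_config(8000, prevalence = mix, discriminability = 4,
                   mode = "class_conditional", seed = 2022), labels)
cohort$subject_id <- sprintf("subj%04d", 1 + seq_len(nrow(cohort)) %% 1200)

parts <- split_train_calibration(cohort, calibration_fraction = 0.10, seed = 1)
calibrator <- mondrian_calibrate(parts$calibration)
#> <mondrian_calibrator> classes: benign (n=441), ISUP1 (n=166), ISUP2 (n=64),
#>                       ISUP3 (n=30), ISUP4 (n=56), ISUP5 (n=47)

test <- simulate_scores(
  synthetic_config(794, prevalence = mix, discriminability = 4,
                   mode = "class_conditional", seed = 794), labels)
regions <- predict_regions(calibrator, test,
  c(benign = 0.85, ISUP1 = 0.85, ISUP2 = 0.67,
    ISUP3 = 0.67, ISUP4 = 0.67, ISUP5 = 0.67))
tally_regions(regions, test$true_label)
#> <evaluation_report> n = 794 | overall efficiency 80%
#>          category benign ISUP1 ISUP2 ISUP3 ISUP4 ISUP5 all
#>             error     12     4     3     2     5     3  29
#>             empty     47    21     9    14     9    11 111
#>    correct_single    335   163    46    20    44    29 637
#>  correct_multiple      9     6     0     0     1     1  17
```

Reading the report: 80% of regions are correct singletons (the efficiency);
111 + 17 = 128 predictions (16%) are flagged for human review (empty or
multiple); the error row — non-empty regions missing the truth — is bounded
per class by the chosen significance levels (15% for benign/ISUP1, 33%
elsewhere), and here sits far below them because many exclusions of the true
label end as empty (flagged) rather than erroneous regions.

A temperature distortion of the scores (T = 1.3, a stand-in for an external
scanner) is caught by the Kolmogorov–Smirnov drift test, and the power curve
says how few deployment examples suffice:

```r
shifted <- apply_shift(test, shift_spec("temperature", 1.3), seed = 3)
drift_test(calibrator, shifted, mode = "labeled")
#> <drift_test_result> D = 0.2175, p = 1.11e-16 (asymptotic, labeled mode,
#>                     n_cal = 804, n_test = 794)
#> Drift detected at alpha = 0.05

power_curve(calibrator, shifted, n_grid = c(10, 25, 50, 100, 200),
            n_reps = 200, seed = 4)
#> <power_curve> threshold 0.8; minimal detecting sample size: 50
#>    n power n_reps alpha
#>   10 0.165    200  0.05
#>   25 0.495    200  0.05
#>   50 0.915    200  0.05
#>  100 1.000    200  0.05
#>  200 1.000    200  0.05
```

The whole chain — simulate, split, calibrate, predict at several confidence
specifications, tally, curve, drift, power, manifest with file hashes — runs
from one YAML config:

```r
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "conformalqc"))
run_pipeline(cfg, "my_run")
```

or from the shell via
`Rscript inst/scripts/conformalqc-cli.R run-all --config <yaml> --out-dir <dir>`
(subcommands: `simulate`, `calibrate`, `predict`, `evaluate`, `curve`,
`drift`, `power`, `run-all`).

See the methods vignette (`vignettes/conformal-qc-methods.Rmd`) for the
model, the generator's assumptions, and all numerical design choices.

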