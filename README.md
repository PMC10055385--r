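# tpmrisk

Temporal phenomic maps and convolutional risk prediction for psoriatic
arthritis (PsA) from longitudinal claims data.

## What this package does, and for whom

Psoriatic arthritis develops in a substantial minority of psoriasis (PsO)
patients and destroys joints irreversibly; catching it ~6 months early
changes outcomes. `tpmrisk` is for epidemiologists and clinical ML
researchers who want a complete, tested, claims-only screening pipeline:

* **Cohort construction** under the study rules — a *case* is a PsO patient
  with ≥2 outpatient ICD-9-CM 696.0 diagnoses on distinct dates or ≥1
  admission claim, with PsO (696.1/696.8) strictly before the first PsA
  code; index date = first PsA diagnosis (cases) or last record (controls);
  eligibility = age 5–99, ≥156 weeks of records, the full analysis window
  observed before the index; controls sampled 1:4, seeded.
* **Temporal phenomic map (TPM) encoding** — codes truncated to categories
  (ICD-9-CM → 3 characters, 1098 rows; ATC → 5 characters, or 7 when the
  5th is "X", 830 rows), then a `1928 × 131` matrix per patient: weekly
  diagnosis counts and prescription days over a 131-week observation window
  that ends 25 weeks before the index, normalized per row into [0, 1] with
  training-set statistics.
* **The CNN** — 8 hidden layers: conv(32 filters, 1×131, ReLU) → avg-pool
  2×2 → conv(2 filters, 1×131, ReLU) → max-pool 1×3 → flatten →
  concat(age, sex) → dense(128, LeakyReLU) → dropout(0.3) → sigmoid;
  Adam, binary cross-entropy, 20 epochs, batch 64. Implemented from scratch
  on BLAS matrix products (convolution as a banded matmul), gradient-checked
  against finite differences.
* **Evaluation** — 80:20 holdout + stratified 5-fold cross-validation;
  AUROC as the tie-corrected Mann–Whitney statistic (with bootstrap or
  Hanley–McNeil CIs); optimal threshold = the observed score maximizing
  sensitivity + specificity; confusion-matrix metrics.
* **Feature importance** — occlusion sensitivity (zero a code's rows,
  rescore with the *same* model, report relative AUROC loss) and
  logistic-regression odds ratios for identified predictors.
* **Synthetic data** — the original population (Taiwan's national claims
  database) is not redistributable, so a seeded generator with planted
  ground truth (risk codes at elevated rates inside cases' observation
  windows) makes every stage testable end-to-end.

The statistic at the core: for patient *i* with map `X_i ∈ [0,1]^{1928×131}`
and auxiliaries `(age_i/100, sex_i)`, the network outputs
`p_i = P(PsA within 25 weeks after the observation window)`, evaluated by
`AUROC = P(p_case > p_control) + ½·P(tie)`, with the operating threshold
`t* = argmax_t {sens(t) + spec(t)}` over observed scores.

## Worked example

A small synthetic world (60 cases, 1:4 controls) with one planted signal:
code "714" (rheumatoid-arthritis-like inflammatory arthritis) occurs 5× more
often inside future PsA cases' observation windows. Windows are scaled to
26/5 weeks with the visit rate scaled up by 131/26, so each map carries
full-window statistical density (see the methods vignette).

```r
library(tpmrisk)

cfg <- sim_config(n_cases = 60, seed = 42, risk_codes = c("714" = 5),
                  visit_rate = 0.5 * 131 / 26,
                  observation_weeks = 26, prediction_weeks = 5)
pop <- simulate_population(cfg)

windows  <- window_spec(26, 5)
criteria <- cohort_criteria(min_record_span_weeks = 31,
                            enrollment_start = "1999-01-01")
cohort <- build_cohort(pop$claims, pop$demographics, criteria, windows)
table(cohort$label)
#>    case control
#>      60     240

tpm <- build_tpm_set(pop$claims, cohort, vocabulary_from_claims(pop$claims),
                     windows)
tpm
#> <tpm_set> 300 maps of 35 rows x 26 weeks (60 case / 240 control)

res <- crossvalidate(tpm,
                     split_plan(holdout_fraction = 0.2, n_folds = 5, seed = 1),
                     model_spec(epochs = 15, batch_size = 16, seed = 7),
                     ci_boot = 500)
res
#> <eval_result> cross-validation folds:
#>  fold n_val auroc threshold sensitivity specificity   ppv   npv
#>     1    48 0.980    0.4919       0.889       0.974 0.889 0.974
#>     2    48 0.969    0.0578       1.000       0.897 0.692 1.000
#>     3    48 0.818    0.3861       0.800       0.789 0.500 0.938
#>     4    48 0.982    0.2372       0.900       0.974 0.900 0.974
#>     5    48 0.968    0.2332       1.000       0.868 0.667 1.000
#> summary (mean, SD over folds):
#>       metric  mean     sd
#>        auroc 0.943 0.0702
#>  sensitivity 0.918 0.0845
#>  specificity 0.901 0.0777
#>          ppv 0.730 0.1677
#>          npv 0.977 0.0257
#> holdout (n=60): AUROC 0.932 (95% CI 0.847-0.995), threshold 0.378, sens 0.92, spec 0.90

norm <- fit_normalization(tpm, sort(unlist(res$split$folds)))
held <- apply_normalization(tpm, norm, res$split$holdout)
head(rank_features(res$final_model, held,
                   feature_groups_from_codes(tpm$vocab)), 3)
#>   feature auroc_full auroc_occluded loss_percent
#> 1     714  0.9322917      0.6111111  -34.4506518
#> 2     460  0.9322917      0.9288194   -0.3724395
#> 3     729  0.9322917      0.9288194   -0.3724395
```

Reading the output: the per-fold table is the cross-validation protocol
(each fold's AUROC, its own optimal threshold, and the confusion metrics at
that threshold), the summary row gives mean/SD over folds, and the holdout
line is the final model retrained on all training data and scored once on
untouched patients. The importance table shows that occluding the planted
code "714" costs the model a third of its discrimination (−34.5% relative
AUROC loss) while occluding background codes costs essentially nothing —
the pipeline recovers exactly the signal that was planted.

Command-line mirror of the same pipeline:

```sh
echo '{"n_cases": 15}'                   > sim.json
echo '{"vocabulary": "claims"}'          > tpm.json   # compact vocab for a demo
echo '{"epochs": 3, "batch_size": 16}'   > train.json
Rscript inst/cli/tpmrisk.R simulate --config sim.json --seed 42 --out pop/
Rscript inst/cli/tpmrisk.R build-cohort --claims pop/claims.csv \
    --demographics pop/demographics.csv --seed 42 --out cohort.csv
Rscript inst/cli/tpmrisk.R build-tpm --claims pop/claims.csv \
    --cohort cohort.csv --config tpm.json --out tpm/
Rscript inst/cli/tpmrisk.R train --tpm tpm/ --config train.json --seed 7 --out model/
Rscript inst/cli/tpmrisk.R evaluate --model model/ --tpm tpm/ --out metrics/
Rscript inst/cli/tpmrisk.R importance --model model/ --tpm tpm/ --out importance.csv
```

(The default `build-tpm` vocabulary is the full 1928-row one; for large
cohorts that is an array of gigabytes, so demos use the claims-derived
compact vocabulary.)

## Further reading

`vignettes/tpm-methods.Rmd` documents the model and its assumptions, every
design decision the source left open (normalization, padding, week
alignment, threshold ties, occlusion semantics), what the synthetic
generator does and does not emulate, and the density-preserving scale-down
used by the acceptance suites.
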