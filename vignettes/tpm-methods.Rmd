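---
title: "Temporal phenomic maps and convolutional PsA risk prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal phenomic maps and convolutional PsA risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Psoriatic arthritis (PsA) develops in a sizeable minority of psoriasis (PsO)
patients and causes irreversible joint damage; a six-month head start on the
diagnosis changes outcomes. `tpmrisk` implements a claims-based screening
pipeline: from longitudinal diagnosis (ICD-9-CM) and prescription (ATC)
records of PsO patients, predict who will receive a first PsA diagnosis
(ICD-9-CM 696.0) half a year ahead, using only codes, dates, age and sex.

The pipeline has five stages, each a module with its own contract:

1. **synth** — a seeded synthetic-claims generator with planted ground truth.
   The original study population (Taiwan's NHIRD, 1999–2013) cannot be
   redistributed, so every downstream stage is exercised against simulated
   populations whose structure mirrors what the analysis assumes.
2. **cohort** — case/control construction. A *case* is a PsO patient with at
   least two outpatient 696.0 diagnoses on distinct dates or at least one
   admission claim, whose first PsO code (696.1/696.8) strictly precedes the
   first PsA code; the index date is the first PsA diagnosis. *Controls* have
   PsO, no qualifying PsA pattern, and their index date is their last
   available record. Eligibility: age 5–99 at index, ≥156 weeks of records,
   index inside 2002–2013, and the full analysis window observed before the
   index. Controls are sampled 1:4 per case, seeded.
3. **vocab_tpm** — the temporal phenomic map (TPM). Codes are truncated
   (ICD-9-CM to its 3-character category, 999 numeric + 99 V-codes = 1098
   rows; ATC to 5 characters, or 7 when the 5th character is "X", 830
   synthetic formulary rows), and each member's observation window becomes a
   1928 × 131 matrix: weekly claim counts for diagnoses, weekly covered days
   for prescriptions, normalized into [0, 1].
4. **model** — an 8-hidden-layer CNN: conv(32 filters, 1×131, ReLU) →
   average-pool 2×2 → conv(2 filters, 1×131, ReLU) → max-pool 1×3 → flatten
   → concatenate(age, sex) → dense(128, LeakyReLU) → dropout(0.3) → sigmoid.
   Trained with Adam on binary cross-entropy, 20 epochs, batch 64.
5. **eval / importance** — 80:20 holdout plus stratified 5-fold
   cross-validation, AUROC (tie-corrected Mann–Whitney), threshold selection
   by maximum sensitivity+specificity, confusion metrics; and
   occlusion-sensitivity importance (zero a code's rows, rescore with the
   same model, report relative AUROC loss) with logistic-regression odds
   ratios for identified predictors.

## Window geometry

Weeks are exact 7-day blocks counted backward from the index date. With
`W = 131` observation weeks and `P = 25` prediction weeks, column `w`
(1-based; column 1 is the oldest week) covers day lags
`delta = index − date` in `[(W + P − w) · 7 + 1, (W + P − w + 1) · 7]`; lags
of 25 weeks or less (the prediction window) and events after the index
contribute nothing. A prescription's days supplied are spread day-by-day
from its start date, so a 14-day script starting 30 weeks before index
contributes 7 + 7 days to two adjacent columns, and only in-window covered
days count. Overlapping scripts of one code can exceed 7 days/week; the
normalization clip absorbs this.

## Choices the source left open

* **Normalization** (scheme unstated): per-row maxima fitted on the
  *training* maps only; the transform divides by the row maximum (all-zero
  rows stay zero) and clips to [0, 1]. This preserves each code's temporal
  shape, guarantees the stated range, and cannot leak holdout information.
* **Week alignment** (unstated): backward from the index in exact 7-day
  blocks, so the observation window ends exactly 25×7 days before the index.
* **Convolution padding**: the printed layer shapes are arithmetically
  inconsistent under valid padding (a 1×131 window cannot follow 2×2 pooling
  of a 131-wide map), so the time-axis convolutions use same padding; with
  toy input shapes the kernel length follows the input width
  (`kernel_weeks`).
* **Loss and optimizer details**: binary cross-entropy (the standard pairing
  with a sigmoid output); Adam at its conventional 1e-3 rate; LeakyReLU
  negative slope 0.3 (the Keras default, matching the study's toolchain).
  All exposed in `model_spec()`.
* **Auxiliary encoding** (unstated): age divided by 100, sex encoded
  male = 1, both concatenated after the flatten layer.
* **Class imbalance**: no reweighting by default (none is reported); a
  `class_weighting` flag enables inverse-frequency weights.
* **Threshold rule**: candidates are the observed scores (the reported
  threshold, 0.429, is an observed probability); the maximizer of
  sensitivity+specificity is returned, ties broken toward higher
  sensitivity, then the higher threshold. Exhaustive enumeration is the test
  oracle.
* **"Stepwise" elimination**: implemented as independent leave-one-out
  occlusions against the intact baseline, not cumulative removal —
  cumulative losses would be order-dependent and the source figure that
  would disambiguate is unavailable. Relative percent change
  `(occluded − full)/full × 100` is the loss scale, matching the magnitude
  of the reported entries far from and near zero.
* **Control-exclusion code**: the source prints "excluded patients with PsA
  (696.8)", almost certainly a typo for 696.0 since 696.8 is a PsO inclusion
  code in the same sentence; controls are excluded by the PsA *pattern*.
* **Record span**: "at least 3 years of records" is read as last-minus-first
  claim ≥ 156 weeks (claims carry no enrollment table), and the stricter
  window reading is adopted — the full 131+25-week window must fit before
  the index — so every encoded map is fully observed.
* **Eligibility vs enrollment**: the index date must fall inside the
  enrollment interval; the record span itself may begin earlier (the
  1999–2001 lookback is what makes a 2002 index encodable).

## The synthetic world

`sim_config()` states the emulated conditions: calendar 1999-01-01 to
2013-12-31; 1:4 case-control ratio; homogeneous Poisson outpatient visits at
0.5 visits/patient-week; per-visit code probabilities over ~23 common
3-digit diagnoses and ~11 ATC categories calibrated to the reported
aggregate order of magnitude (≈35 diagnosis code-units and ≈45–50
prescription-days per person-year — per-code distributions are not
published and are NOT emulated); days supplied concentrated on 3–7-day
scripts with a chronic-refill tail (support 1..90); case ages ~N(42.7,
17.2²), controls ~N(46.9, 20.2²), truncated to [5, 95], 61%/57% male; 5% of
diagnosis claims are admission claims. Every patient carries recurring PsO
codes with a guaranteed claim at the start of their record; cases get a
qualifying PsA pattern anchored at the true index date (two outpatient
696.0 on distinct dates, or one admission claim, with probability equal to
`inpatient_fraction`) and multiplicatively elevated risk-code rates inside
the observation window (optionally ramping toward the index). Controls
never receive 696.0, and their last record *is* their index date.

What a green test does establish: the pipeline recovers exactly the planted
cases, conserves event counts into map cells, learns a planted
multiplicative signal, and attributes it to the right code under occlusion.
What it does not establish: performance on real claims — the generator has
no comorbidity correlation structure, no coding-practice drift, no
reimbursement semantics, and per-code frequencies are stylized. The study's
real-data numbers (AUROC 0.70, threshold 0.429, the occlusion table) are
not reproducible here and are deliberately not targets.

## Scaled-down acceptance runs

The signal-recovery and importance-recovery suites would need hours at the
full 1928 × 131 scale on one CPU, so they run on a *density-preserving*
scale-down: the observation/prediction windows shrink (52/10, 26/5 or 13/3
weeks), the eligibility span shrinks with them, the vocabulary is built from
the observed claims (~35 rows), and the visit rate scales by `131/W` so each
map carries the same expected in-window event counts — hence the same
statistical content — as the stated full-window world. Without that
compensation a shrunken window silently weakens the planted signal below
the stated condition (we measured exactly this: raw single-code AUROC 0.97
vs 0.998, and a cross-validated mean of 0.84 instead of ~0.95). Cohort
sizes (200 cases / 800 controls), the multiplier-5 planted code, the
published 20-epoch protocol, and every acceptance threshold are kept as
stated. The null-world and importance suites use the same construction at
smaller n with proportionally reduced epochs, since they assert chance-level
behaviour and a ranking, not a performance level.

## Numerical notes

* The CNN is implemented directly on BLAS matrix products (no deep-learning
  backend exists in the target environment, and the network is the method's
  core): a same-padded 1×L temporal convolution is a banded linear map of
  the week axis, so a batch convolves as one matmul of the stacked
  (sample, row) matrix against a banded kernel matrix rebuilt from the
  filter weights each step; the weight gradient folds the kernel-matrix
  gradient back over its bands, and a ones-column/bias-row augmentation
  carries the filter biases. Backprop is verified against central finite
  differences on every layer (relative error < 1e-4 at eps = 1e-6).
* Glorot-uniform initialization, Adam with bias correction (eps 1e-7),
  inverted dropout; all randomness (initialization, shuffling, dropout,
  splits, bootstrap) is seeded and the RNG state of the caller is never
  disturbed.
* Pooling uses valid extents (floor division); odd trailing rows/columns are
  dropped, as in the reference toolchain.
* AUROC ties count 1/2 via the rank formulation; the bootstrap CI is
  stratified (2000 replicates by default) with a Hanley–McNeil normal
  approximation available.
* Degenerate inputs: single-class training or scoring sets raise errors;
  zero-denominator confusion ratios are `NA`, not 0; perfectly separated
  logistic predictors are flagged non-estimable and the run continues;
  unmappable claim codes (e.g. E-codes) are skipped and counted, never
  fatal.

## Known limitations

* Training on the full 1928-row vocabulary at cohort scale takes hours on a
  single CPU; the package is sized for method validation and moderate
  cohorts, not production-scale training.
* The synthetic formulary is a stand-in with the right size (830) and shape,
  not a real drug list; `atc_formulary()` documents this.
* `crossvalidate()` refits normalization per fold but trains each fold from
  a fresh seeded initialization; fold-to-fold variance therefore mixes data
  and initialization variance, as in the emulated protocol.
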