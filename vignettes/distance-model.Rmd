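---
title: "The prescription distance model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The prescription distance model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxanomaly)
```

## The problem and the working assumptions

A radiotherapy prescription is the pair (number of fractions, dose per
fraction in cGy). Prescription errors that survive human peer review tend
to be of two kinds: a prescription that has essentially never been used
(e.g. a digit transposition that preserves total dose), and a common
prescription delivered to the wrong kind of patient (wrong intent, wrong
primary site, an age band the scheme is never used in). The distance model
turns both into geometry: a new course is flagged when it is too far from
its closest historical neighbours, either in prescription space (type I)
or in the clinical-feature space of patients who share its prescription
(type II).

Two assumptions matter. First, the historical database is treated as
error-free: distances measure departure from past practice, so systematic
past errors would be learned as normal. Second, rarity is what the
distances proxy — a larger distance corresponds to a lower empirical
(marginal or prescription-conditional) frequency. Both are approximations;
the model's output is an explained score, not a clinical judgment.

Models are fit per delivery technique (`3d`, `imrt`, `sbrt`), because the
same prescription can be routine in one technique and exceptional in
another. Free-text technique labels are collapsed by a synonym table
(`normalize_technique()`), and cohorts are cleaned before fitting:
calibration entries with zero total dose, re-plan course sets detected by
a mismatch (> 1 cGy, the data's resolution) between total and accumulated
dose, cone-down plans via a plan-linkage column when one exists, records
of unmodelled techniques, and diagnoses outside the configured thoracic
ICD-10 prefix list. Each removal is tagged with a machine-readable reason;
nothing is dropped silently.

## Metrics and decision rule

With `S` historical records, the per-record scores are

- `R(i, m)`: mean of the `m` smallest scaled-Euclidean prescription
  distances to the historical cohort;
- `F(i, n)`: mean Gower feature distance over `n` neighbours selected by a
  two-key sort — prescription distance first, Gower distance second.

The two-key sort realizes "compare against people with the same (or
nearest) prescription": all exact-prescription matches are considered
before anyone else, and when fewer than `n` share the prescription the
selection pads from the next-closest prescription groups. Ties at both
keys are broken by record order; the value of `F` is unaffected because
only the Gower values of the selected set enter the mean, but the
tie-break makes the selection itself deterministic.

Thresholds are multiples of the cohort's characteristic distances,
`t_Rx = a * theta`, `t_F = b * tau`, with `theta` and `tau` the mean
pairwise distances over all ordered pairs `j != k` (the `S(S-1)`
normalizer excludes self-pairs). Flagging is strict (`>`): a score exactly
at its threshold passes. On the type I branch `F` is not computed and is
reported as `NA`, never as 0, so a downstream consumer cannot misread a
skipped value as a good one. When a record that is itself part of the
index is scored in-sample, it is excluded from its own neighbour pools and
counts (`exclude_id` / `exclude_self`), otherwise its self-distance of
zero would mask any anomaly.

## Tunable parameters

| parameter | meaning | default / box | notes |
|---|---|---|---|
| `mu` | `m = round(mu * S)`, prescription pool | `(0, 0.1]` | floor at 1; round half away from zero |
| `nu` | `n = round(nu * S)`, feature pool | `(0, 0.1]` | same rounding |
| `a` | `t_Rx = a * theta` | `(0.01, 2]` search box | covers fitted values seen in practice |
| `b` | `t_F = b * tau` | `(0.01, 2]` search box | |

The 10% cap on `mu`, `nu` keeps the neighbour pools local. The rounding
rule (half away from zero, floored at 1) is a convention this package
fixes explicitly, since `m` and `n` must be positive integers whatever
`S` is. Wider `mu`/`nu` are permitted at inference only via
`model_params(validate = FALSE)`.

Training (`tune()`) maximizes f1 — the standard
`tp / (tp + (fp + fn)/2)`, anomalies positive — on a fixed set of
simulated anomalies plus holdout normals resampled `n_repeats` times from
a pool that is *disjoint from the index*: `theta`, `tau` and the neighbour
pools never see the evaluation data. The per-candidate objective is the
mean over resamples; the returned result also reports its standard
deviation. The resampled holdouts are drawn once, up front, from the run
seed, and reused for every candidate: traces are exactly reproducible and
candidates are compared on identical data, which removes between-candidate
resampling noise from the search. Reference-scale defaults are 100
evaluations averaged over 50 resamples; the examples and tests in this
package run desk-scale configurations (30 evaluations x 10 resamples on
cohorts of 500), which the end-to-end results show are already sufficient
for stable recovery.

Three search strategies are provided: an adaptive sampler (default) that
splits evaluated trials at the top-quartile f1, models good and bad trials
per dimension with Gaussian kernel mixtures and picks the fresh draw with
the best good/bad density ratio — the tree-structured-Parzen-estimator
idea in its simplest form — plus pure random search and a factorial grid.
Every acceptance property holds under all three; the adaptive sampler
merely finds good candidates in fewer evaluations.

## Simulated anomalies and rarity verification

The positive class is synthesized from real (or generated) records by
three mutators:

1. `switch_rx_digits()` — swap the leading decimal digits of fractions
   and dose per fraction (5 fx × 400 → 4 fx × 500); total dose is often
   preserved, which is exactly what makes such errors hard to see. No-op
   swaps are rejected, and so are swaps landing on a historically common
   prescription. Applying the swap twice restores the original.
2. `mutate_features()` — redraw chosen feature fields from their global
   historical domains, accepting only values whose co-occurrence count
   with the record's exact prescription is at or below the rarity ceiling
   (default 0: never happened; a ceiling of 1 reproduces "occurred only
   once" cases). For age, "co-occurrence" is counted within ±5 years,
   because exact equality on a continuous field is vacuously rare; the
   band is configurable.
3. `switch_technique()` — relabel the technique so the record is scored
   against another technique's cohort. Here the rarity question is
   different: the whole feature set moves at once, and the mutation is a
   meaningful anomaly as soon as *some* feature is out of place for that
   prescription in the target cohort (the canonical case: a beam energy
   that the target technique essentially never uses with that
   prescription). Requiring *every* feature to be rare would reject
   exactly the realistic cases, so acceptance requires at least one
   verified-rare field, and only those fields are recorded as evidence.

`verify_rarity()` is the shared checker: per changed field, the count of
historical records sharing the mutated record's exact prescription (dose
rounded to integer cGy) and the field's value; for prescription changes,
the count of the new prescription itself. Every emitted anomaly carries
this evidence, so the label "anomalous" is always backed by counts, not by
authorial intuition — mutators are purely data-driven and encode no
clinical knowledge.

## The synthetic cohort generator

Real treatment records are restricted, so `generate_cohort()` draws
cohorts with the structure the detector actually relies on: a small
catalog of prescriptions with very unequal weights (so exact-prescription
repeats are common and `R = 0` is the normal case), and feature
distributions conditioned on the prescription — some prescriptions are
curative-only, use one energy, treat one site. Defaults per technique use
fractionation schemes standard in thoracic practice (5×400, 10×300,
25×180, 30×150, 10×250, 5×1000, 4×1200, ...), ages as per-prescription
truncated normals, and small per-feature missingness rates (2–20%,
morphology highest, as is typical of record exports). Courses are
single-plan (`accumulated = total = fractions × dose`), so a generated
cohort passes the cleaning rules untouched.

What the generator does **not** emulate: secular trends in practice (e.g.
a hypofractionation shift over years), correlated multi-course patients,
free-text noise in labels, within-prescription feature correlations
beyond the conditional tables, and real-world rates of historical errors.
Passing end-to-end tests on these cohorts therefore demonstrates that the
pipeline recovers planted, verified-rare mismatches under clean
conditions — a necessary check, not evidence about any particular clinical
database.

`plant_anomalies()` assembles the evaluation design: `k` mutated positives
and `n_normals` holdout normals, with both the sources of the positives
and the holdout removed from the historical set before the index is
built, so nothing the model is scored on contributes to its statistics.

## Numerical choices and degenerate inputs

- Prescription scaling uses historical min/max only; out-of-range new
  patients scale outside [0, 1] by design. A degenerate field
  (min = max) scales to constant 0 with a warning.
- Gower excludes fields missing in either record and renormalizes; a pair
  with no comparable fields is an error in the pairwise API and an
  excluded pair (with a warning) in the `tau` computation.
- Prescription equality for counts and grouping is exact after rounding
  dose to 1 cGy; "similar" prescriptions are handled by the two-key sort,
  not by fuzzy equality.
- `theta`/`tau` are permutation-invariant means; the implementation's
  cumulative-mean profile (`R` and `F` for all `m`, `n` in one pass) is
  tested for exact agreement with brute-force oracles on hundreds of
  random cohorts.
- The tuner evaluates candidates on precomputed distance profiles — valid
  because the profiles do not depend on the hyperparameters — and a test
  pins the fast path to the plain `detect()`-based evaluation.
- Problem sizes in tests and the acceptance script (cohorts of 500, 60
  anomalies, 30 x 10 tuning) were chosen as the smallest configuration at
  which recovery results are stable across seeds.

## Known limitations

- The model inherits whatever biases the historical cohort has; it cannot
  flag an error type that was historically routine.
- Thresholds tuned on simulated anomalies transfer to real anomalies only
  insofar as real errors look like the mutators' output; the digit-switch
  and conditional-mismatch families cover the documented error anatomy,
  but not, e.g., wrong-site errors invisible in these seven fields.
- Very rare but legitimate prescriptions are indistinguishable from
  type I anomalies by construction; the prescription count in every
  detection is there precisely so a reviewer can see "rare but seen
  before" at a glance.
- `F` is meaningful only when some historical patients share (or nearly
  share) the prescription; the insufficient-history warning marks
  verdicts that rest on padded neighbour groups.
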