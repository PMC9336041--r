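---
title: "Methods: blood-ctDNA biomarkers and the tumour mutation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-ctDNA biomarkers and the tumour mutation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TMIstrat)
```

## The problem

Second-line NSCLC patients treated with single-agent chemotherapy
(docetaxel) or a checkpoint inhibitor (atezolizumab) differ widely in
overall-survival benefit, and plasma ctDNA sequencing offers a biopsy-free
way to stratify them. TMIstrat implements a family of ctDNA biomarkers and
a composite index built from them:

* **bTMB** — the count of a patient's somatic ctDNA mutations classified
  missense, synonymous, splice or nonsense;
* **sbTMB** — the subset count restricted to missense and splice;
* **UMS** — the *unfavourable mutation score*, a weighted count of
  "unfavourable" genes identified by per-gene survival screening;
* **TMI** — the *tumour mutation index*, a sum of stratum-specific
  hazard-ratio scores across five clinical characteristics and the three
  biomarkers above.

All four are turned into binary responder / non-responder labels through
cut-offs chosen by exhaustive log-rank p-value minimisation, and those
labels are evaluated with Kaplan-Meier medians, log-rank tests,
Mantel-Haenszel hazard ratios and landmark ROC analysis.

## Counting rules

bTMB counts *mutation rows*, not mutated genes: two missense calls in the
same gene contribute 2. Mutations whose effect class falls outside the five
recognised labels are mapped to `other` and count toward neither burden.
This rowwise convention is the natural reading of "number of mutations" for
a targeted panel and is asserted in the unit tests; panels that wish to
collapse per-gene can deduplicate the mutation table before
`computeBurdens()`.

## The unfavourable-gene screen and UMS

For every gene carried by at least `minCarriers` patients (default 3 — a
log-rank comparison against one or two carriers is numerically legal but
meaningless), carriers and non-carriers are compared by log-rank on the
chosen endpoint. A gene is retained when

* its p-value falls in the screening window `[0, 0.3)`, and
* the carrier Mantel-Haenszel HR exceeds 1 (the *unfavourable* direction —
  the p-window alone would also admit protective genes).

Retained genes receive scores by left-closed p-value bins:
`[0, .05) → 5`, `[.05, .10) → 4`, `[.10, .15) → 3`, `[.15, .20) → 2`,
`[.20, .30) → 1`. A patient's UMS is the **sum** of scores over the
*distinct* retained genes they carry (a gene mutated twice counts once).
Summation is the only aggregation consistent with UMS cut-offs such as
"UMS ≤ 9" exceeding the maximal single-gene score of 5. The per-gene
p-values are deliberately not multiplicity-adjusted — the screen is a
score-construction device, not an inference — and this statistical liberty
is inherited by everything downstream; the permutation-adjusted scan p
(`permutationAdjustedP()`) is the tool for honest significance claims.
Whether the screen should use log-rank or Cox p-values is an open
modelling choice; we use log-rank so that the screen, the scans and the
comparisons all share one test.

## Cut-off scans

`scanSingleCutoff()` tests every distinct observed biomarker value `c`
whose split `value ≤ c` vs `value > c` leaves at least `minGroupFrac`
(default 0.10) of patients on each side, and returns the argmin of the
log-rank p. `scanDualCutoff()` enumerates every ordered pair `c1 < c2`
with responders `value ≤ c1 | value > c2`, capturing the U-shaped response
seen with checkpoint-inhibitor burden biomarkers (both very low and very
high burden do better than the middle band). The exhaustive pair search
subsumes sequential "first cut-off, then intersection" heuristics, whose
exact meaning is under-specified; with `c2` at the maximum observed value
the dual rule reduces exactly to the single rule, which the tests assert.

Numerical choices: the group floor prevents degenerate argmins at extreme
tails (no floor is a documented deviation knob — set it near `1/n` to
disable); ties on p break toward the larger responder group, then the
smaller `c1`, then the smaller `c2`, so scans are deterministic; the full
`(cut-off, p)` trace is kept on the fitted object for diagnostics.

## Survival machinery

Kaplan-Meier estimation and the hypergeometric-variance log-rank statistic
come from the `survival` package (ties handled hypergeometrically in the
log-rank, Efron-style in Cox; a fixture test pins this behaviour). The
median is the first time the curve reaches 0.5 (`S(t) ≤ 0.5`), and is
reported as undefined (`NA`) when censoring floors the curve above 0.5.
The default HR estimator is Mantel-Haenszel,

$$\widehat{HR} = \frac{O_A/E_A}{O_B/E_B},\qquad
  \mathrm{CI}_{95} = \widehat{HR}\,e^{\pm 1.96\sqrt{1/E_A + 1/E_B}},$$

computed from the pooled log-rank observed/expected events — the estimator
behind the Prism-style workflows in which biomarker HRs of this kind are
conventionally produced — with the univariable Cox estimate as an option.
The two agree within 15% on proportional-hazards simulations at n ≥ 500
(asserted in tests); they can differ materially under non-proportionality.

## The TMI model

Within each stratum of the five clinical characteristics — sex, smoking
history, histology (LUSC / non-LUSC), driver-gene status, and the
metastasis dichotomy at `< 3` vs `≥ 3` sites — and for each biomarker, the
optimal cut-off is scanned and the responder-vs-non-responder HR recorded:
up to 5 × 2 × 3 = 30 components. Strata smaller than `minStratum`
(default 20 — below that the scan's log-rank approximations and the
group floor both break down) are skipped with a flag.

Scoring uses the `hr_if_responder` rule: for each (characteristic,
biomarker) pair, a patient accumulates the component HR of *their own
stratum* when they satisfy that component's responder rule, and 1.0
otherwise — including when the characteristic is unknown or the component
was skipped, making unknowns exactly neutral. The TMI is the sum of the 15
terms, so with favourable components (HR < 1) lower TMI means better
predicted prognosis. The precise functional form of an "HR score" is a
genuinely open design point; `hr_if_responder` is our default because it
makes low TMI monotonically track membership in favourable groups
(alternatives such as signed log-HR would score favourable and unfavourable
strata symmetrically but lose the "sum of HRs" reading). Patients are
split at the **median TMI of the discovery cohort**, ties to the low
group (the ≤ convention used by every other cut-off here), and that
threshold — with the discovery gene table feeding UMS — is *frozen* when
the model is applied to a validation cohort. Component fitting uses OS by
default; PFS is available.

## Evaluation

The responder-prediction ROC needs a binary outcome that trial tables do
not directly provide; the default is a landmark outcome — alive beyond a
landmark (commonly the arm's median OS) is positive, an event at or before
it negative, and patients censored before the landmark are excluded (not
imputed) and counted. AUC is computed by trapezoid with a DeLong
(rank-based, large-sample) CI and a null test of AUC = 0.5 from the same
variance; orientation is chosen so AUC ≥ 0.5 and reported. Subgroup HR
tables flag (rather than compute) subgroups with fewer than 10 patients
per comparison arm. The burden-by-response comparison is a classical
unpaired Student t test (Welch optional).

## The synthetic-cohort generator

The generator emulates an OAK-like second-line trial arm and defines the
conditions under which the pipeline is tested:

| parameter | default | rationale |
|---|---|---|
| patients | 300 | a single trial-arm BEP (~320) |
| panel | 300 genes | targeted ctDNA panel scale |
| mutations/patient | NB(mean 10, size 2) | ctDNA call counts are overdispersed; median burden ~8-10 |
| effect mix | 0.55 / 0.25 / 0.05 / 0.10 / 0.05 | missense-dominated spectrum (missense, synonymous, splice, nonsense, other) |
| covariates | male 0.6, smoker 0.8, LUSC 0.25, driver+ 0.15, metastasis sites Pois(2.2) | advanced-NSCLC prevalences |
| baseline hazard | 0.087 / month | exponential OS, ~8-month median |
| censoring | 0.02 / month | light, independent administrative censoring |
| PFS | OS × Beta fraction (mean 0.5) | progression precedes death, noisily |

Survival is exponential (constant baseline hazard) under proportional
hazards — the simplest PH-compatible choice, so planted multipliers are
exactly the true HRs; planted effects multiply the hazard above a biomarker
cut-off, inside a middle band, or for carriers of designated genes, and
covariates are independent of biomarkers by default so component effects
are attributable. One global seed drives fixed per-stage sub-seeds
(counts, effects, genes, planted carriers, covariates, survival,
censoring, PFS, response), so adding a later stage never perturbs earlier
draws and every cohort regenerates byte-identically.

What the generator does **not** emulate — mutational signatures, panel
footprints and allele frequencies, covariate-biomarker correlation (a knob
exists), non-proportional or non-exponential hazards (a Weibull shape is
the natural extension), informative censoring — bounds what passing tests
show: they demonstrate that the estimators recover what was planted under
the stated model, not that the model describes any particular trial.

## Test and simulation scales

Oracle-equivalence checks run exact permutation enumeration at n ≤ 10 and
brute-force scan enumeration at ≤ 50 distinct values. Recovery and
calibration properties use 10-50 seeded replicates at n = 300-600, the
scale at which the planted effects (HR ≥ 2) are comfortably detectable;
the end-to-end composite-index recovery uses one discovery cohort of 600
and a frozen-model validation cohort of 200, mirroring a
discovery/validation split of roughly 3:1.

## Known limitations

* Scan p-values are optimised, hence anti-conservative; only
  `permutationAdjustedP()` corrects for the search.
* The Mantel-Haenszel CI uses the `1/E_A + 1/E_B` variance, slightly wide
  when one group dominates the risk sets.
* The per-gene screen is unadjusted for multiplicity by design (see above).
* Reproducing published trial-cohort thresholds requires the externally
  deposited trial tables; `publishedCutoffs()` ships the printed constants
  so such a run can apply them directly, but the package does not download
  data.
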