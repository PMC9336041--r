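# TMIstrat

Blood-ctDNA biomarker construction and survival stratification for
advanced NSCLC treated with second-line docetaxel or atezolizumab.

Plasma ctDNA sequencing yields a per-patient table of somatic mutation
calls without a tissue biopsy. TMIstrat builds the biomarkers that turn
such a table, joined with trial clinical data, into responder /
non-responder labels with measurable overall-survival separation:

* **bTMB** — blood tumour mutation burden: the count of a patient's
  mutations classified missense, synonymous, splice or nonsense;
* **sbTMB** — the subset restricted to missense and splice;
* **UMS** — unfavourable mutation score: per-gene carrier-vs-non-carrier
  survival screening retains genes with log-rank *p* < 0.3 and carrier
  HR > 1, scores each by p-value bin (`[0,.05)→5 … [.2,.3)→1`), and sums a
  patient's distinct carried gene scores;
* **TMI** — tumour mutation index: within each stratum of five clinical
  characteristics (sex, smoking, histology, driver-gene status,
  metastasis sites < 3 vs ≥ 3) and for each biomarker, an optimal cut-off
  and its responder hazard ratio are fitted; a patient's TMI is

  TMI = Σ over (characteristic, biomarker) of { HR of own stratum if the
  patient satisfies its responder rule, else 1 },

  split low/high at the discovery-cohort median (frozen for validation).

Cut-offs are found by exhaustive log-rank *p* minimisation over observed
values — a single threshold (responders `value ≤ c1`) or a dual U-shaped
rule (`value ≤ c1 | value > c2`) for checkpoint-inhibitor burden
biomarkers. Group comparisons report Kaplan-Meier medians, the log-rank
test, and the Mantel-Haenszel hazard ratio
`(O_A/E_A)/(O_B/E_B)` with its `exp(±1.96·√(1/E_A+1/E_B))` CI (Cox
optional). A seeded synthetic-cohort generator with planted cut-off,
U-shape and unfavourable-gene effects makes every stage testable without
trial data.

## Worked example

Fit the full pipeline on a simulated discovery arm in which patients with
bTMB > 10 carry twice the hazard:

```r
library(TMIstrat)

sim <- simulateCohort(simConfig(nPatients = 600, seed = 7L,
  plantedSingleCutoff = list(biomarker = "btmb", cstar = 10,
                             multiplier = 2.0)))
co <- sim$cohort
co
#> MutationCohort: 600 patients, 5895 mutations
#>   arms: docetaxel 600

b     <- computeBurdens(co)
genes <- screenUnfavourableGenes(co)
u     <- computeUMS(co, genes)
model <- fitTMI(co, b, u)
model
#> TMIModel (docetaxel, OS)
#>   components: 30 fitted, 0 skipped
#>   score rule: hr_if_responder
#>   median TMI threshold: 9.5381

res <- applyTMI(model, co, b, u)
print(res$comparison, digits = 3)
#>   n_a n_b median_a median_b chi_square  p_value    hr hr_ci_low hr_ci_high
#> 1 300 300     8.55     3.59       88.4 5.48e-21 0.456      0.38      0.548
```

Low-TMI patients (n = 300) have a median OS of 8.55 months against 3.59
for high-TMI patients, with a Mantel-Haenszel HR of 0.46 (95% CI
0.38–0.55) — the composite index recovers the planted favourable group
(true HR 0.5 for the low-burden majority). Applying `model` with
`applyTMI()` to a fresh cohort scores it with the *frozen* median
threshold and discovery gene table; `subgroupHRTable()`,
`rocAuc(defineOutcome(...))` and `efficacySummary()` evaluate the labels.
File-based runs (`runSimulate()`, `runFit()`, `runApply()`) read a YAML
configuration, write TSV reports and a manifest, and reproduce
bit-for-bit. `publishedCutoffs()` ships the printed OAK/POPLAR thresholds
(e.g. dual bTMB ≤ 7 or > 20 for atezolizumab) for reproduction runs
against the externally deposited trial tables.

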