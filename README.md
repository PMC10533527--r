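# svbn — Bayesian network risk analysis for single-ventricle CHD cohorts

`svbn` is an R package for quantifying how genetic, demographic, and
clinical variables — alone and in combination — change the probability of
adverse neurodevelopmental and growth outcomes in cohorts of children with
single-ventricle congenital heart disease (SV-CHD). It is aimed at
biostatisticians and clinical researchers working with dichotomized cohort
tables (developmental index scores, length-for-age z-scores, genotype
flags, perinatal covariates) who want joint, synergy-aware risk estimates
rather than one-variable-at-a-time effect sizes.

## The method

A complete, dichotomized cohort is modeled as a discrete Bayesian network.
The pipeline:

1. **Dichotomization** at fixed published thresholds (MDI/PDI ≤ 70,
   LAZ ≤ −1.6 adverse; MDI/PDI > 100, LAZ > 0 favorable; birthweight
   < 2500 g; ventilation > 7 d; gestational age < 37 wk; SES < −0.3), or
   data-driven outcome thresholds selected by an ROC-AUC grid search.
2. **Exact structure learning**: the DAG maximizing the decomposable BIC
   score `LL − ½·ln(N)·#params` is found by dynamic programming over
   variable subsets (best parent set per candidate set, best sink per
   subset) — the exact optimum, not a heuristic. CPTs are fitted as
   posterior means under a uniform Dirichlet prior (pseudocount 1; pure
   MLE available).
3. **Risk queries**: for outcome A and risk variables B, C, …

   ```
   RR = P(A = true | B = true, C = true) / P(A = true | B = false, C = false)
   ```

   computed by exact variable elimination, with unlisted variables
   marginalized. Confidence intervals are 5th/95th percentiles of the RR
   recomputed on networks relearned from bootstrap resamples of the cohort.
4. **Group comparisons**: two-sided Mann–Whitney U tests with Bonferroni
   correction.

The patient-level cohort that motivated this design is access-restricted
(dbGaP), so the package includes a synthetic cohort generator
(`build_preset_network()`, `sample_discrete_cohort()`,
`sample_continuous_scores()`) whose ground-truth networks match the
reported genotype-flag prevalences (44% and 14%); every algorithm is
validated against that ground truth or against brute-force oracles
(all-DAG enumeration, full-joint inference).

## Worked example

```r
library(svbn)

truth  <- build_preset_network("svr_core")
spec   <- synthetic_spec(truth, n_subjects = 1000, seed = 42)
cohort <- as_discrete_cohort(sample_discrete_cohort(spec))

net <- learn_network(cohort)
net$structure
#> <dag_structure> 6 nodes, 5 edges
#>   dGV <- MDI_low
#>   SYNDR <- PDI_low, dGV
#>   PDI_low <- MDI_low
#>   LAZ_low <- SYNDR

scs <- list(
  risk_scenario("MDI_low", "true", c(dGV = "true")),
  risk_scenario("MDI_low", "true", c(PDI_low = "true")),
  risk_scenario("MDI_low", "true", c(dGV = "true", PDI_low = "true")))
ests <- scenario_battery(cohort, scs, n_boot = 200, seed = 7)
forest_table(ests)
#>                                  label    rr ci_lo  ci_hi n_boot n_failed
#> 1              MDI_low=true | dGV=true  6.63  5.03   9.39    200        0
#> 2          MDI_low=true | PDI_low=true 18.14 13.53  24.85    200        0
#> 3 MDI_low=true | dGV=true,PDI_low=true 86.26 27.69 131.83    200        0
```

Reading the output: a damaging genotype flag (`dGV`) alone raises the
probability of a low Mental Developmental Index about 6.6-fold over its
absence, a low Psychomotor Developmental Index alone about 18-fold, but the
*combination* raises it about 86-fold — far beyond either factor alone,
which is the synergy the network queries exist to expose. The learned edges
are a Markov-equivalent re-orientation of the generating structure (BIC
cannot distinguish within an equivalence class), and the single-factor
estimate brackets the generator's true ratio of 7.79. Intervals are 5th and
95th bootstrap percentiles across 200 relearned networks.

The same stages run as a configured pipeline
(`run_pipeline("pipeline.yaml")`, or `Rscript inst/cli/svbn.R run --config
pipeline.yaml`), which writes the discrete cohort, network JSON, risk
estimates, a plot-ready forest table, and a checksummed manifest; identical
config and seed give byte-identical artifacts.

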