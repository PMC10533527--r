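---
title: "Bayesian network risk analysis for single-ventricle CHD cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian network risk analysis for single-ventricle CHD cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svbn)
```

## The problem

Children born with single-ventricle congenital heart disease (SV-CHD) face
staged palliative surgery and a high burden of neurodevelopmental and growth
impairment. Individual predictors — damaging genotypes, prematurity, low
birthweight, prolonged post-operative ventilation, socioeconomic status —
have modest marginal effects, but they act *jointly*: the probability of a
poor outcome under a combination of risk factors is not the product of the
single-factor effects. `svbn` models a dichotomized cohort as a discrete
Bayesian network and quantifies those joint effects as
conditional-probability relative risks.

The analysis pipeline is:

1. **Dichotomize** continuous outcomes and clinical covariates at fixed,
   previously published thresholds (or select an outcome threshold by
   ROC-AUC grid search).
2. **Learn** the exact BIC-optimal network structure over the binary
   variables, and fit conditional probability tables (CPTs).
3. **Query** the fitted network: for an outcome $A$ and risk variables
   $B, C, \dots$,
   $$\mathrm{RR} = \frac{P(A = \text{true} \mid B = \text{true},\,
   C = \text{true})}{P(A = \text{true} \mid B = \text{false},\,
   C = \text{false})},$$
   with every unlisted variable marginalized. Uncertainty comes from a
   percentile bootstrap over networks relearned on resampled cohorts.
4. **Compare groups** with Mann–Whitney U tests under Bonferroni
   correction.

The patient-level data that motivated this design are access-restricted, so
the package ships a synthetic cohort generator with known ground truth;
every stage is validated against that truth or against brute-force oracles.

## Dichotomization

Threshold rules are literal inequalities. The built-in rule sets are:

| variable | rule | flagged label |
|---|---|---|
| MDI, PDI (Bayley-II points) | ≤ 70 | `low` |
| LAZ (z-score units) | ≤ −1.6 | `low` |
| MDI, PDI (favorable mode) | > 100 | `normal` |
| LAZ (favorable mode) | > 0 | `normal` |
| birthweight (g) | < 2500 | `low` |
| ventilation after Stage I (days) | > 7 | `prolonged` |
| gestational age (weeks) | < 37 | `preterm` |
| SES score (US-census units) | < −0.3 | `low` |

Adverse-mode and favorable-mode dichotomization are separate runs producing
separate discrete cohorts; a three-state encoding is deliberately avoided
because the risk queries condition on binary states. Boundary behaviour is
exact: MDI = 70 is `low`, VENT = 7 is `not_prolonged`, MDI = 100 is
`not_normal` under the favorable rule.

Missing data are handled only by complete-case filtering
(`filter_complete_cases()`); there is no imputation. Missing-token parsing
(`""`, `"NA"`, `"NaN"`, case-insensitive, configurable) is cosmetic because
incomplete rows never reach the network stages.

## Structure learning

The network score is the decomposable BIC in natural-log units,

$$\mathrm{BIC}(G) = \sum_v \left[\hat\ell(v \mid \mathrm{pa}_G(v)) -
\tfrac{1}{2}\ln(N)\, q_v \right],\qquad
q_v = (|\mathcal{S}_v| - 1)\prod_{p \in \mathrm{pa}_G(v)} |\mathcal{S}_p|,$$

where $\hat\ell$ is the maximized multinomial log-likelihood (with the
$0\ln 0 \equiv 0$ convention) and larger is better. No smoothing enters the
score: the likelihood inside the BIC is pure MLE, as standard.

`exact_structure_search()` maximizes this score exactly by dynamic
programming over variable subsets: best parent set per (node, candidate
set), best sink per subset, then order reconstruction. The result equals
the maximum over *all* DAGs under the parent cap, which the test suite
verifies against full enumeration (543 DAGs on four nodes). The cap
defaults to `max_parents = 3` — the cohort networks have ≤ 10 nodes, so
exact search stays comfortable while the cap bounds CPT size; the oracle
tests run effectively uncapped. The subset DP visits every variable subset,
so the search guards at 18 variables and asks for a variable subset beyond
that.

Ties between equal-scoring DAGs are real (Markov-equivalent structures tie
exactly under BIC) and are broken deterministically: per family, fewer
parents, then the lexicographically smallest parent-name set; per subset,
the lexicographically smallest sink. All name comparisons use C collation,
so results do not depend on the session locale. This local rule yields a
canonical optimum; in principle a multi-way tie could admit another DAG
with the same score and a lexicographically smaller global edge list, which
we accept for the per-family guarantee and determinism.

## Parameter fitting

CPT entries are $(\text{count} + \alpha) / (\text{total} + \alpha\,
|\mathcal{S}_v|)$ with pseudocount $\alpha = 1$ by default — the posterior
mean under a uniform Dirichlet prior, reading the usual "uniform prior"
convention for discrete networks. $\alpha = 0$ gives pure MLE but turns
unseen parent configurations into an error rather than a silent undefined
row; with $\alpha > 0$ an unseen configuration yields the uniform
distribution. The positive default matters for the bootstrap: resampled
cohorts routinely drop rare configurations, and the prior keeps every
replicate's relative risk defined.

## Inference

Queries are exact. `query()` runs variable elimination with a min-fill
elimination order (deterministic tie-break by node name);
`brute_force_query()` enumerates the full joint (guarded at $2^{20}$
configurations) and is shipped as the testing oracle — the suite checks
agreement below $10^{-10}$ on random networks. We deliberately use an exact
algorithm rather than loopy belief propagation: on networks of this size
exactness is cheap, and it is testable against enumeration without an
approximation gap. Evidence with probability zero raises an error instead
of returning `NaN`, because silent `NaN`s would corrupt relative-risk
ratios downstream.

## Relative risks and the bootstrap

`relative_risk()` computes both arms by exact query: the numerator
conditions every listed risk variable on its flagged state, the denominator
conditions *all* of them on their complements simultaneously, and unlisted
variables are marginalized, never conditioned. Two consequences follow
directly and are tested: an outcome d-separated from the risk variables has
RR exactly 1, and swapping flagged/complement states of every risk variable
maps RR to 1/RR.

`bootstrap_ci()` and `scenario_battery()` resample rows with replacement to
the original $N$ and relearn **both structure and parameters** per
replicate — "networks from bootstrap replicates" is read as distinct
networks, and refitting only parameters would understate uncertainty. The
interval is the 5th/95th percentile of the surviving replicate ratios (a
90% percentile interval, matching the 5-and-95% convention of the source
analyses; the abstract-style "±95%" phrasing is not used). Replicates with
an undefined ratio are discarded and counted in `n_failed`, never imputed.
The point estimate comes from the full-data network; percentile intervals
are not guaranteed to bracket it, and both are reported without
reconciliation.

Reproducibility is structural: replicate $b$ draws its row indices from a
sub-seed derived from `(seed, b)` only, so batteries share one replicate
stream across scenarios (estimates are comparable, duplicates are
identical) and extending `n_boot` never perturbs earlier replicates.
`n_boot` defaults to 1000; the validation suite uses 200 with the
corresponding Monte-Carlo slack.

## Cutoff selection by ROC-AUC grid search

`optimize_cutoff()` reproduces the outcome-threshold search: for each
candidate cutoff the target is dichotomized, the network is relearned on
the resulting cohort (structure and parameters — the labels change the
data, so freezing a structure would leak an arbitrary choice), each subject
is scored with the exact conditional probability of the flagged state given
their other variables, and the AUC of scores against induced labels is
recorded. The argmax is returned; ties prefer the more balanced class
split, then the smaller cutoff. Candidates inducing an empty class or a
class below `min_class_size` (default 5) are skipped with a reason. The
default grid uses integer steps over the observed range (0.1 steps are
appropriate for z-score-scaled targets such as LAZ); outcome targets are
optimized independently, not jointly.

Two caveats are inherent to this procedure and documented deliberately.
First, scoring reuses the data the network was fit on — there is no
cross-validation — so AUCs are optimistic in the usual in-sample sense.
Second, that optimism is *not uniform across candidates*: cutoffs deep in
the tail induce a very small flagged class that the relearned network can
separate almost perfectly in-sample, so their AUCs can exceed the AUC at
the true latent boundary. Under the generator's default conditions
(Gaussian emissions 60/100 with SDs 7/10 around a latent class of
prevalence ≈ 0.18, $n = 1000$, integer grid, `min_class_size = 5`) the
validation battery shows exactly this: the selected cutoff sits near the
latent boundary in most seeds, but in a minority of seeds a tail cutoff
with a 8–15-subject flagged class wins the argmax outright. In addition,
even the Bayes-optimal cutoff misclassifies ≈ 0.8% of subjects in
expectation under these emissions, so near-perfect (≥ 99%) label agreement
sits within one binomial standard deviation of the optimum and cannot be
achieved reliably. The acceptance battery reports the recovery rate as
measured rather than relaxing it; practitioners should scale
`min_class_size` with the cohort (e.g. a few percent of $N$) and restrict
the grid to a clinically plausible band, both of which the API exposes.

## Group comparisons

`mann_whitney_u()` wraps the standard two-sided rank-sum test: the exact
permutation p-value when $n_1 n_2 \le 400$ and the pooled sample is
tie-free, otherwise the normal approximation with tie and continuity
corrections (the switch threshold is ours; the field convention is silent).
The U statistic counts first-group wins with ties at ½, which makes the
identity $\mathrm{AUC} = U/(n_1 n_2)$ exact — the suite checks it to
$10^{-12}$ against the ROC module. Bonferroni correction multiplies by the
family size and caps at 1; the family size is always an explicit argument
(the analyses this mirrors do not print theirs).

## The synthetic cohort generator

The generator is first-class, tested code: a ground-truth network plus
ancestral sampling, optional per-column missingness, and optional Gaussian
emissions that attach a continuous score to a latent binary state (the
latent column is retained under `latent_<target>` for recovery testing).

The `svr_core` preset emulates the statistical structure the analysis
assumes, with all CPTs fixed constants of the package (printed in
`?build_preset_network`): genotype-flag prevalences 0.44 (`dGV`) and 0.14
(`SYNDR`) matching the reported cohort; outcome CPTs chosen once so that
(a) every dependency is comfortably detectable at $n = 500$ — edges near
the BIC detection threshold would make bootstrap relearning erratic for
reasons unrelated to the method — and (b) the `MDI_low` CPT contains a
supra-multiplicative interaction (0.02 / 0.30 / 0.10 / 0.85), the quantity
the synergy queries exist to measure. The implied low-MDI prevalence
(≈ 0.18) is in the range reported for Bayley assessment in this
population. `SEX` is kept isolated, providing an exact d-separation fixture
(its states are `false`/`true` with `true` denoting female, matching how a
binary cohort column would be encoded). `svr_clinical` adds prematurity,
birthweight, ventilation and SES with a chain of clinical dependencies and
a three-parent outcome CPT. `chain_test`, `collider_test` and
`independent_test` are the three-node fixtures used throughout the
examples.

What the generator does **not** emulate: the real cohort's full joint
distribution, enrollment criteria, survival bias, continuous-score shapes
beyond unimodal-per-class, or any variant-calling upstream of the binary
genotype flags. Passing the validation battery therefore demonstrates
correctness of the algorithms under known ground truth — not that the
package would reproduce the published cohort estimates, which require the
restricted data.

## Problem sizes and numerical choices

The validation battery uses: 20 × 543-DAG enumeration oracles at $n = 200$;
50 random-network inference cross-checks (≤ 8 nodes); parameter recovery at
$n = 20{,}000$ (±0.02 on cells with expected count ≥ 100); chain recovery
at $n = 5000$ over 20 seeds; cutoff recovery at $n = 1000$ over 20 seeds;
bootstrap coverage over 100 cohorts of $n = 500$ with 200 replicates each.
These sizes give binomial/Monte-Carlo error small enough for the stated
bounds while keeping the battery at desk scale.

Numerical conventions: CPT rows validate to 1 within $10^{-12}$; query
distributions within $10^{-10}$ of the enumeration oracle; percentiles use
the default type-7 quantile; JSON serialization writes full precision and
round-trips byte-identically; all RNG flows through a single integer seed
via fixed sub-seed derivation, so every artifact is bit-reproducible.

## Known limitations

- Relative risks are conditional-probability ratios on the fitted network —
  not causal effects; there is no do-calculus or adjustment-set logic.
- In-sample AUC optimism in the cutoff search, as analyzed above.
- Exact search is exponential in the number of variables (by design;
  heuristic search is out of scope), so analyses beyond ~18 variables must
  pre-select a subset.
- Only binary/categorical nodes: continuous variables enter through
  dichotomization, never as hybrid nodes.
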