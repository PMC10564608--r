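---
title: "Methods behind nova24r: recall processing, agreement statistics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind nova24r}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nova24r)
```

nova24r implements the computational core of a web-based, self-administered
24-hour dietary recall built around the Nova food-processing classification:
a food database with a branching question graph, deterministic recall
processing (portion resolution, fractional imputation of skipped fields,
recipe disaggregation, Nova energy shares), a reviewer adjudication workflow,
and the agreement statistics used to compare two recall tools on the same
participants. This vignette documents the models and the reasoning behind the
package's default parameters.

## The food database and question graph

A `food_db` holds six tables: items, recipes, composition, portions,
questions and options, plus a manifest with expected structural counts.
Items come in three kinds:

* **individual** — maps directly to one composition code;
* **grouped** — a set of interchangeable foods ("fresh fish: salmon, tuna,
  sardine") represented for coding purposes by a single *representative*
  member's composition code;
* **preparation** — a dish with no code of its own, resolved by recipe
  disaggregation.

Questions form a forest rooted at *key* questions ("Did you eat fish
yesterday?"). Follow-ups (*type_amount*, *added_item*, *preparation*,
*detail*) are triggered only when the parent was answered and, where a
trigger option is declared, only by that answer. Every item is owned by
exactly one key question, so the instrument can be validated structurally:
`validate_counts()` compares observed counts of items and questions per type
against the manifest. The bundled `fixture_food_db("paper_shape")` generator
reproduces a realistically sized instrument — 57 key questions, 190
type/amount, 47 added-item, 19 preparation and 82 detail questions (395 food
questions in all) over 526 items (347 individual/grouped, 179 preparations,
10 of which use adapted rather than standard recipes). These counts are
fixed by the generator's deterministic partition, not tuned at run time.

## Recall processing

`process_session()` converts a finalized session into consumption records in
four deterministic steps:

1. **Portion resolution.** Each answered food-binding option carries a
   portion; grams = portion grams × reported units (1 unit when the amount
   was not asked).
2. **Refinement.** Detail/preparation questions that refine the reported
   item either override the composition code (when answered) or, when
   skipped, split the mass *fractionally* over all options using population
   distributions. The split uses `split_exact()`: every share but the last
   is rounded ordinarily and the last share absorbs the floating-point
   remainder, so mass is conserved *exactly*, not just to tolerance. The
   canonical example: 100 g of honey bread with unknown origin becomes
   20.4 g homemade, 28.0 g bakery and 51.6 g packaged under the population
   distribution (0.204/0.280/0.516) — three records with different Nova
   groups rather than one record under a modal assumption. Fractional
   imputation was chosen over modal imputation because the downstream
   outcome (energy share by Nova group) is linear in mass, so the fractional
   estimator is unbiased under the stated population distribution while the
   modal one is not.
3. **Disaggregation.** Preparations resolve to their recipe ingredients in
   stated mass fractions. Fractions are renormalised at load when they miss
   unit sum by more than 1e-9 (with a classed warning), so disaggregation
   also conserves mass exactly.
4. **Composition join.** Energy is grams × kcal/100 g; kJ-valued tables are
   converted at 4.184 kJ/kcal on load.

`nova_shares()` then reports each participant's percentage of total energy
from each Nova group — the study's outcome metric. Shares are `NA` (flagged
`zero_energy`) when a session contributes no energy, rather than silently 0.

## Agreement statistics

Two tools measuring the same participants are compared on three axes.

**Paired means.** `compare_means()` runs a paired t-test (or Wilcoxon)
per Nova group on the share scale, with per-tool means and confidence
intervals. Differences whose standard deviation is numerically negligible
are reported as degenerate (point confidence interval, `NA` p-value) instead
of forcing a test that is undefined.

**ICC.** `icc_two_way()` implements the two-way model with tools as raters.
The default form is *consistency*, ICC(3,1) = (MS~R~ − MS~E~) /
(MS~R~ + (k−1) MS~E~), because a systematic level shift between two recall
instruments is expected and is already tested separately by
`compare_means()`; *absolute agreement* (ICC(A,1), McGraw–Wong) is available
when the level shift should count against agreement. Confidence intervals
are exact F-based for consistency and the McGraw–Wong approximation for
absolute agreement. The implementation is verified in the test suite against
an independent `stats::aov` mean-squares oracle to 1e-10 and by parameter
recovery with nominal CI coverage. Bands follow the 0.50/0.75/0.90
convention (poor/moderate/good/excellent).

**Quintile cross-classification.** `quintile_agreement()` assigns fifths per
tool and reports exact and adjacent agreement plus PABAK =
(5·P~o~ − 1)/4, the prevalence- and bias-adjusted kappa for five categories.
The default split is rank-based (`dplyr::ntile`): with heavy ties — common
for Nova group 2 shares, which are often zero — quantile thresholds can
empty a quintile, so the quantile mode detects that condition, warns, and
falls back to ranks. Bands follow the modified Landis–Koch scale with
`almost_perfect` above 0.80.

**Sample size.** `icc_sample_size()` is the Walter–Eliasziw–Donner
approximation: with θ = ρ/(1−ρ) and C₀ = (1+kθ₀)/(1+kθ₁),

n = 1 + 2k (z₁₋α + z₁₋β)² / ((k−1) (ln C₀)²),

rounded up. α is one-sided because the design question is directional (is
agreement better than the null value, not merely different). At ρ₀ = 0,
ρ₁ = 0.2, k = 2, α = 0.05 and power 0.80 this gives 152 subjects — the
package's acceptance target, recomputed at run time by
`scripts/acceptance.R`.

## The synthetic cohort

`cohort_spec()` defines a simulated validation study. Defaults describe a
plausible adult web cohort: 186 participants, 55% women, 61% from the
southeast/northeast macro-region, mean age 41.3 (SD 13), 30% overweight and
24% obese, and an education mix of roughly 5/46/49% across three levels.
The missingness default 23/186 ≈ 0.124 is the fraction of participants for
whom at least one imputable field is skipped, applied per eligible question.

Paired shares are generated with an **additive-log-ratio (alr) normal
latent model**: for participant *i* and tool *t*, the three alr coordinates
(log share~g~/share~4~) are μ~g~ + b~i,g~ + ε~i,t,g~ with
b ~ N(0, σ²~between~) and ε ~ N(0, σ²~within~), then mapped back to the
simplex so every simulated profile sums to exactly 100. μ is chosen so the
*mean* shares match the spec's defaults (52.3/11.6/17.1/19.0% for Nova
groups 1–4). A tool-level bias vector `bias_b` can shift tool B on the share
scale to exercise `compare_means()`.

The implied agreement of this model, ρ = σ²~between~ / (σ²~between~ +
σ²~within~), holds on the **alr scale**. On the share scale the nonlinear
inverse-alr map attenuates the correlation when the latent variances are
large, so share-scale ICCs sit below the implied value while remaining
strictly monotone in it. The test suite therefore checks exact recovery
(±0.03) on the alr scale and monotone tracking on the share scale, rather
than asserting a share-scale equality that the model does not imply. The
defaults σ~between~ = 0.8 and σ~within~ = 0.45 give an implied alr-scale ICC
of about 0.76 — in the "good" band where a validated recall instrument is
expected to land — while keeping the attenuation mild.

`simulate_session_pairs()` goes one level deeper: it plays two full recall
sessions per participant through the question engine against a real
`food_db`, with a `fidelity` parameter controlling how often the second
session repeats the first session's answers. This exercises the entire
pipeline (engine → processing → shares → ICC); the suite checks that
recovered agreement rises with fidelity and exceeds 0.7 at fidelity 0.95 on
an 80-participant cohort, sizes chosen to keep the property informative yet
fast.

## Problem sizes used in verification

The package's own test suite fixes its Monte-Carlo sizes as follows: ICC
oracle equality on 100 random tables with n ≤ 20; recovery/coverage at
n = 500, k = 2 with 1000 replicates per true ρ ∈ {0.3, 0.55, 0.75, 0.9};
PABAK null behaviour at n = 5000 (|PABAK| < 0.02); pipeline conservation
over 1000 simulated sessions to 1e-9; and null calibration of
`compare_means()` at n = 186 over 2000 replicates (rate in [0.04, 0.06]).
These are verification choices of this package, sized so each suite finishes
in minutes while leaving the statistical assertions well inside their
sampling noise.

## Limitations

* The synthetic cohort is a *model* of a validation study, not data from
  one; its alr-normal latent structure is convenient, not estimated.
* The two-way ICC assumes no subject-by-tool interaction beyond the residual
  term; with k = 2 this is not separately identifiable.
* Quintile agreement with rank-based splits is undefined up to tie-breaking
  order for exactly tied values; ties are broken by position, which is
  deterministic but arbitrary.
* The food database fixtures are structurally faithful (counts, graph shape,
  recipe logic) but their composition values are synthetic; the package does
  not ship real food-composition data.
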