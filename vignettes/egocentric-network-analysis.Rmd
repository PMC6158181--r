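---
title: "Egocentric network metrics and outcome association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egocentric network metrics and outcome association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egonets)
```

## The data model

A structured personal-network instrument yields, per respondent (*ego*):
demographics (age in years, sex, marital status, years of education, a
two-level diagnosis group), eight outcome domain items each scored 0–4
(total 0–32), an *uncapped* name-generator count, and — for the first ten
named alters only — pairwise tie strengths on three levels (stranger,
weak, strong) plus per-alter attributes: sex, age, race, and ten tri-state
flags (kin, supportive, contacted at most weekly, known under six years,
living more than fifteen miles away, smokes, does not exercise,
medication-non-adherent, no regular doctor visits, perceived negative
health influence).

`ego_network` stores this as a symmetric integer tie matrix over
{ego} ∪ alters with entries 0/1/2 and a typed alter attribute table.  Two
conventions matter:

* **Ego ties are definitional.**  The ego named every alter, so ego–alter
  entries are fixed present (coded strong).  They are excluded from
  density and degrees — otherwise every degree would inflate by exactly
  one — but participate in constraint, whose definition requires the
  ego's own proportional investments.
* **Missing pairwise items are conservative zeros.**  A skipped tie
  question becomes "no tie", with the count kept on the network
  (`missing_ties`) and aggregated into a cohort missingness rate, so the
  choice is auditable.  A `reject` policy (route the row to the rejects
  report instead) is available in `survey_config()`.

All column names, category encodings and missing-value codes live in
`survey_config()`, so the parser is not bound to one export dialect.
Rows violating hard invariants (outcome item outside 0–4, missing or
negative name count, unrecognised tie code) go to a rejects report with
reasons; the parser never throws on malformed rows, and
`accepted + rejected = input rows` always holds.

## Metrics

Structure metrics binarise ties: a tie is present iff weak or strong.
This matches how density is conventionally reported (percent of possible
ties); strength is retained for serialization and figures, and a
`weighted` switch lets constraint use weights weak = 1, strong = 2
instead.  Size is the uncapped named count; everything else is computed
on the ≤ 10 detailed alters, because only they carry pairwise data.
With a median size of 8 and median density near 67%, the expected alter
degree is about `0.67 × 7 ≈ 4.7`, which is why degrees must exclude the
ego tie to land near the mean-degree medians such instruments report.

Burt's constraint is implemented from its definition,
`C = Σ_j (p_ej + Σ_q p_eq p_qj)²` with `p` row-normalised weights on the
ego-inclusive graph, reported ×100.  Effective size uses the binary
simplification `n − 2t/n`, which equals the full redundancy sum
`Σ_j (1 − Σ_q p_eq m_jq)` on binary symmetric graphs; the test suite
verifies both against brute-force oracles on *every* graph with up to
five alters (and random graphs up to six) to 1e-9, and cross-checks
constraint against igraph's independent implementation.

Compositional percentages divide by the number of alters with a
*non-missing* answer for that item, not by raw size: unknown habits
should not deflate a percentage.  The denominators are exported alongside
(`n_*` columns) for audit.  Degenerate networks propagate `NA` (density
needs two alters; constraint, effective size, degrees one; age spread two
known ages), and `NA` rows drop out of regressions case-wise.

The diversity of sex and race uses the index of qualitative variation
`(1 − Σ p²)/(1 − 1/k)`, anchored at 1 for an even mix and 0 for a
uniform network; `k` is the instrument's category count (2 for sex, the
configured race list length for race).  A normalised IQV cannot exceed 1,
yet published race-diversity tails above 1 exist; those imply a
differently-normalised index whose exact form is not recoverable.  We
keep the normalised IQV as primary and expose the unnormalised Blau index
(`normalize = FALSE`, maximum `1 − 1/k`) for comparison.

The "unhealthy alter" composite flags an alter who smokes, does not
exercise, skips regular doctor visits, *or* is medication-non-adherent:
any observed true dominates (even with other flags missing), all-observed
false gives false, all four missing gives `NA`.  The perceived
negative-influence item is a separate survey question and is kept as its
own metric.

## Association analyses

Each network variable is the exposure in an ordinary least-squares model
of the outcome, adjusted for age, sex, marital status and years of
education (`COVARIATES_FULL`; `COVARIATES_REDUCED` drops education for
the minimal-adjustment variant — both appear in practice, so the choice
is a switch).  P-values are two-sided; FDR is Benjamini–Hochberg within
each category batch (6 structure, 13 composition), matching how the
multiple-testing burden is grouped.

The omnibus test asks whether a category associates with the outcome *as
a group*: combine the per-variable p-values into Fisher's
`X² = −2 Σ ln p` and compare against the distribution of the same
statistic under permutations of the outcome across respondents.
Permuting the outcome rather than the predictors preserves the
correlation structure among the network variables, which is what makes
the df-2m chi-squared reference invalid and the permutation reference
necessary.  Conventions:

* Rows with missing outcome or covariates are dropped first; each
  variable's regression then uses its own complete cases, with permuted
  outcome values drawn from the common pool.  Permutation indices attach
  to outcome values in table row order, so reordering rows redraws the
  Monte Carlo pairing (the observed statistic is exactly invariant; the
  empirical p moves only within Monte Carlo error).
* The empirical p is the plain fraction of permuted statistics strictly
  greater than the observed one; with `N` permutations it can therefore
  be an exact zero, reported as `< 1/N`.  The bias-corrected estimate
  `(1 + #{perm ≥ obs})/(N + 1)` is computed alongside and is the better
  choice whenever the p-value feeds further inference.
* P-values are floored at 1e-300 before logs, so a numerically zero
  p-value cannot produce an infinite statistic.
* One RNG stream per test, seeded explicitly; the seed is stored in the
  result and in every serialized JSON, which is byte-identical across
  runs with the same inputs and seed.

Permutation refits are vectorised: each variable's design matrix is
QR-decomposed once and all permuted outcomes are solved in one pass, so
10,000 permutations over 19 variables on ~1,500 rows take about a second.

QQ plots show sorted observed −log10 p against the medians of uniform
order statistics (`qbeta(0.5, i, m−i+1)`).  The envelopes are *pointwise*
per-rank quantiles across permutations: the 90% band spans the 5th–95th
percentile (the chance range at a threshold of 0.10), the 95% band the
2.5th–97.5th.  Pointwise bands have ~95% per-rank coverage by
construction; the probability that *all* m ranks fall inside
simultaneously is lower (about 80% for m = 13 in our null simulations),
which is the expected behaviour of pointwise — as opposed to simultaneous
— envelopes, and how the tests assert them.

Group descriptives use Welch's t (age), chi-squared (dichotomous items),
and the Wilcoxon rank-sum test (skewed quantities), the latter exact when
both groups have at most ten untied observations and mid-rank/tie
corrected otherwise.  A Spearman correlation against the outcome is
provided as the non-parametric sensitivity companion to the regressions.

## The synthetic cohort

`sim_params()` defaults define the study conditions the generator
emulates, chosen once from the cohort marginals such instruments report:

| quantity | model | default | rationale |
|---|---|---|---|
| ego age | normal | mean 38.3, sd 8.4 y | cohort demographics |
| male / married | Bernoulli | 0.193 / 0.67 | cohort demographics |
| diagnosis group | Bernoulli | 7.7% MS | cohort mix |
| network size | negative binomial | mu 9, dispersion 6 | quartiles 6/8/12 match the reported size median 8, IQR [6, 12] |
| tie density | Beta per ego | (1.73, 1) | median 0.67; ties then Bernoulli per pair, giving realistic cohort spread |
| habit prevalences | per-alter Bernoulli | e.g. smoke 0.10, no exercise 0.33, no doctor 0.07, negative influence 0.12 | reproduce the composition medians |
| race | ego-dominant with 7% defection | homophily 0.93 | race-diversity median 0 |
| outcome | linear in centred metrics + noise, clamped to [0, 32], rounded | intercept 1.2, noise sd 2.2 | clamping at a low intercept yields the floor-heavy right skew of the real instrument |

The outcome total is decomposed into eight 0–4 domain items by capped
multinomial allocation, so emitted CSVs carry valid item-level data.
Injected metric effects enter centred at the realised cohort mean
(missing metrics contribute zero), so OLS on the raw metric recovers the
injected slope.  All draws flow from one seed; `emit_survey_csv()` output
is byte-identical across runs and parses back with zero rejects to
networks equal to the in-memory ones on every field.

Presets: `"null"` (no effects anywhere — calibration), `"paper-like"`
(composition effects at the reported magnitudes, structure null, MS shift,
floor skew), `"strong-effect"` (larger composition effects with the
outcome centred mid-scale: intercept 10, noise sd 3).  The last exists
because a floor-censored outcome attenuates OLS coefficients by
construction; parameter-recovery and power studies therefore run in the
interior regime, where ±2 SE coverage of an injected effect is a fair
expectation.  This is a property of linear models on censored scales, not
of the implementation.

The generator emulates *marginals and injected effects only*.  It does
not simulate homophily dynamics, social contagion, clustered missingness,
or any dependence of network structure on the outcome — so passing
calibration tests demonstrates that the machinery is correct and
calibrated under the stated conditions, not that real cohorts satisfy
those conditions.

## Scales used by the test suite

Chosen to give stable Monte Carlo verdicts in minutes on one core:
omnibus type-I error over 200 null cohorts of 300 egos with 1,000
permutations over all 19 variables (rejection rate must land in
[0.03, 0.07] at α = 0.05); recovery of an injected 0.017 effect on the
negative-influence percentage over 200 cohorts of 1,400 egos (±2 SE
coverage ≥ 93%); null p-value uniformity by Kolmogorov–Smirnov over 150
seeds; power separation (composition omnibus significant, structure not)
over 40 seeds of the strong-effect preset at 400 egos.

## Known limitations

* Detailed metrics see at most ten alters; for larger networks density,
  constraint and composition describe the observed core, while only size
  reflects the full network.
* The race-diversity index is the normalised IQV; values are not
  comparable to analyses that used an index exceeding 1 (see above).
* The omnibus permutation keeps covariates attached to their rows while
  the outcome is shuffled, so the null being tested is "outcome
  exchangeable across respondents", which also severs outcome–covariate
  links; this is the structure-preserving choice for the network
  variables, at the cost of not conditioning on covariate effects.
* Complete-case regressions assume missingness unrelated to the outcome
  given covariates; no imputation is attempted.
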