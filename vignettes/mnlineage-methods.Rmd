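---
title: "Models and methods behind mnlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mnlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnlineage)
```

## The scientific setting

`mnlineage` analyses live-cell imaging experiments in which a fluorescent
reporter switches on when a CRISPR/Cas9 cut at the Xp subtelomere is
repaired as a single sister chromatid fusion (SCF). Marked cells and all
their descendants are tracked through a movie of at least 66 h (frames
every 6–12 min) and every observed cell cycle becomes one record: lineage
and cell identifiers (path labels `a`, `aa`, `ab`, ...), condition labels,
birth / nuclear-envelope-breakdown (NEBD) / division times, interphase and
mitotic durations, and event flags (micronucleus, bi/multi-nucleation,
death, marker fading, tripolar mitosis, furrow regression, cell fusion).
Six experimental conditions arise from cell line (`SIS2-3` carries the
SCF reporter cassette, `CTRL48` a control cassette), treatment (`sgF11`
CRISPR targeting vs. `mCit` mock), and cell-cycle stage relative to
marker onset (`1+x`: the marker appeared during the movie, so the cycle
count since the rearrangement is known up to a small offset; `N+x`:
already fluorescent at movie start).

## Model families

**Micronucleus formation (family 1).** The per-cycle MN indicator is
Bernoulli with a logit link:

$$\mathrm{MN}_n \sim \mathrm{Bernoulli}(q_n), \qquad
q_n = \mathrm{inv\_logit}\bigl(b + scf\,\mathrm{SCF}_n + rnf\,\mathrm{RNF}_n
+ stg\,\mathrm{STG}_n + sis\,\mathrm{SIS}_n + lin_{l(n)}\bigr)$$

with dummy variables SCF (SIS2-3 × sgF11: the cell may carry a fusion),
RNF (CTRL48 × sgF11: cutting and repair without fusion), STG (stage N+x)
and SIS (cell line). The registry `mn_model_registry()` crosses two
linear predictors (all four terms, or `scf` alone) with three
lineage-individuality choices (none, normal, Student-t), named `1_1` to
`1_6`. The naming is a package convention anchored by two fixed points:
`1_2` is the full predictor without lineage effects and `1_4` is the
scf-only model without lineage effects. The exact composition of the
remaining four structures was an open design choice; we order them
(full/normal, full/none, scf/normal, scf/none, full/t, scf/t) and every
output names the specification it used, so any other convention is a
one-line registry change.

**Interphase duration (family 2).** Durations (hours, birth to NEBD) are
log-normal with condition-specific scale:

$$y_n \sim \mathrm{LogNormal}(\mu_n, \varsigma_{c(n)}), \qquad
\mu_n = b + micro\,\mathrm{MN}_n + scf\,\mathrm{SCF}_n + \dots (+ lin_{l(n)})$$

`exp(micro)` is the multiplicative MN effect on the median duration. The
experimental covariates are included as confounders: they causally
precede both MN formation and interphase duration, so fixing them in the
linear predictor lets `micro` estimate the MN → duration effect. The
registry mirrors the MN grid with `micro` always present (`2_1`–`2_6`),
plus `2_2_exp` and `2_2_gamma`, which keep the `2_2` linear predictor but
swap the likelihood. Both alternatives are parameterized so that the mean
is `exp(mu_n)` (exponential rate `exp(-mu_n)`; gamma shape `alpha_c`,
rate `alpha_c/exp(mu_n)`): the source analyses do not print their link
for these likelihoods, so we chose the mean parameterization and isolated
it behind `pointwise_loglik()`, where an alternative is a one-line
change. Records whose NEBD was never observed contribute nothing to
duration likelihoods; records censored during mitosis still contribute
their completed interphase.

**Priors.** Weakly informative defaults: Normal(0, 10) on the bias and
all coefficients, half-Normal(0, 5) on scales (`sigma`, gamma shape,
hierarchical `tau`). Student-t lineage effects use a fixed 4 degrees of
freedom (configurable); the data are unlikely to identify the tail index
of a random-effect distribution at these sizes. Priors are recorded in
every fit object.

## Posterior computation

`fit_lineage_model()` runs an adaptive random-walk
Metropolis-within-Gibbs sampler written in plain R. Scalar parameters
(bias, coefficients, log scales, log `tau`) get individually tuned
Gaussian random-walk updates; the lineage intercepts are conditionally
independent given everything else, so they are proposed as one vector
and accepted/rejected per lineage using per-lineage likelihood sums —
this makes hierarchical fits scale linearly in the number of lineages.
Proposal scales adapt toward ~0.44 acceptance during warmup only, so the
retained draws form a valid Markov chain. Defaults are 4 chains × 2000
iterations with 1000 warmup; initial values are data-informed (logit of
the empirical MN rate; mean and sd of log durations) and jittered per
chain. Convergence is monitored with rank-normalized split-R-hat
(threshold 1.05, attached to the fit as a warning) and a crude effective
sample size. The pointwise log-likelihood matrix needed for WAIC is
evaluated at every retained draw.

On a ~4,100-record dataset the scf-only MN model fits in a few seconds
and the full duration model in under ten; these sizes are what the test
suite and the acceptance script use throughout (twenty replicate
datasets for the recovery studies).

## Model comparison

`waic()` computes, per observation, `lppd_i = log mean_s exp(loglik_si)`
(log-sum-exp stabilized) and the penalty `p_i = Var_s(loglik_si)` with
the n−1 sample-variance denominator — the common estimator in practice;
Watanabe's population form differs by a factor (S−1)/S, which is
negligible at thousands of draws but documented here because it would
show up in cross-tool comparisons at tiny S. Results are reported on the
generalization-loss scale (nat/sample, smaller is better), matching the
per-sample values printed beside each model structure in this kind of
analysis; the deviance-scale value (`2 n × waic`) is also carried.
`compare_waic()` applies the significance rule: a per-sample difference
is meaningful when `|Δ| × n × 2 > 1` on the AIC scale.

## Predictions

`predict_mn_prob()` maps each posterior draw through the inverse logit at
a covariate setting; for hierarchical fits a fresh lineage effect is
drawn per posterior draw, integrating over the lineage population. The
fold change between two settings is the ratio of *averaged*
probabilities (the per-draw ratio distribution is returned alongside):
averaging first matches how mean posterior probabilities are compared
across conditions. `predictive_durations()` samples durations by drawing
a posterior draw, forming `mu`, and sampling the likelihood with the
requested condition's scale; by default it integrates over the posterior
(`integrate = FALSE` plugs in posterior medians — both modes exist
because point-estimate predictive plots are common in this literature).
Quartiles and IQR use empirical type-7 quantiles (linear interpolation);
the IQR of predictive duration distributions is the package's measure of
cell-cycle stability. Kolmogorov–Smirnov distances between predictive
samples use the standard two-sample statistic; at the default 10,000
samples per side the p-value saturates and is display-only.

## Sister pairs

`find_matched_pairs()` emits a pair for every bipolar division whose two
daughter subtrees differ in MN status (exactly one side contains an
MN-positive cell; the whole daughter subtree counts, not only the
daughter itself). Each side is tallied for additional abnormalities: MN
events beyond the index one, regression, fusion, death, mitotic delay
(a mitosis strictly longer than 2 h), and "fewer mitoses" scored against
the side that divided less. The side with the strictly larger tally is
"more abnormal"; ties count in neither cell of the resulting 2×2 table
(the source convention for ties is not stated; strict majority is ours).
`chisq_2x2()` is the Pearson test without continuity correction (flag
available), and `event_probability()` reports the MLE k/n alongside
Jeffreys and Laplace posterior means and the Jeffreys median, because a
printed probability of this kind can originate from any of them.

## The synthetic-data generator

`simulate_lineages()` inverts the two model families into a branching
process, with the within-cycle causal order MN first, duration second.
Defaults are the study conditions the models target:

| parameter | default | why |
|---|---|---|
| lineages per condition | 50 | ~300 trees, matching the scale of the real tree census (167 + 138) |
| movie length | 66 h | minimum tracking window of the imaging protocol |
| frame interval | 10 min | middle of the 6–12 min acquisition range |
| `b` (MN baseline) | logit(0.0102) | baseline per-cycle MN probability 0.0102 |
| `scf` | 2.44 | posterior median of the SCF effect; gives P(MN) = 0.106 with SCF |
| `rnf`, `stg`, `sis2-3` | 0 | reported as minor or no effects |
| `b` (duration) | log(20) h | 20-h cycle, typical HCT116 doubling time; together with the tree census this yields ~4,100–4,350 records, matching the real n = 4,424 |
| `micro` | 0.820 | posterior median of the MN effect on log duration |
| `ς` per condition | 0.3 | realistic log-scale spread for cultured-cell cycle times |
| mitosis | log-median log(0.5), sd 0.2 | ~30-min mitoses |
| lineage-effect sd | 0 | the non-hierarchical truth matches the winning model structures; set > 0 to exercise hierarchical fits |
| death / fusion / bi-multi / tripolar / regression | 0.01 / 0.005 / 0.005 / 0.003 / 0.005 per cycle | plumbing defaults for rare events, not measured rates |
| onset window (1+x) | 22 h | founders acquire the marker in the first third of the movie |

Founders of N+x lineages are present from frame 0; 1+x founders appear at
a uniform random onset. Root cells are emitted without an interphase
duration: the marker switches on mid-cycle, so only a residual interphase
is visible and treating it as complete would bias duration fits. In
SIS2-3 sgF11 1+x lineages exactly one daughter of the first division
loses the marker (the single reporter gene segregates to one daughter),
mirroring the ~50% marker loss seen experimentally; the faded branch is
emitted as one terminal record and never observed further. Sister-cell
fusion merges the two daughters and ends their observation; a furrow
regression produces a single binucleate daughter. All times are kept as
integer frame counts internally, so every emitted time is an exact
multiple of the frame interval; durations are at least one frame.

What the generator does **not** emulate: fluorescence intensities,
chromatin-bridge mechanics, chromothripsis, death-rate dependence on MN
status, inter-lineage cell fusion, and any drift of event rates over the
movie. Passing recovery tests on these simulations therefore shows that
the inference machinery is correct under the stated generative
assumptions — not that the assumptions hold in real movies.

## Movie-end truncation: a known, quantified limitation

Cycles still in progress when the movie ends are censored, and the
models (like the analyses they reimplement) simply exclude unobserved
durations rather than modelling censoring. This observation process is
*length-biased*: a cycle is observed only if it fits between the cell's
birth and movie end, so long cycles — in particular MN-lengthened ones,
with median `exp(micro) ≈ 2.27` times the baseline ~20 h — are
preferentially lost. At the default study conditions only ~12% of
MN-positive cycles complete on screen, and the observed MN+/MN−
log-duration gap is ~0.65–0.70 rather than the generative 0.820. Fits of
model `2_2` to default simulations therefore centre `micro` around
0.60–0.75, and their 95% intervals usually exclude the generative value:
the estimator is consistent for the *truncated-data* effect, not the
latent one. The package leaves this bias in place deliberately —
censoring-aware duration modelling is out of scope, and the bias is a
property of the study design worth seeing — and the test suite verifies
the generator's duration law on early-born cells (births with ≥ 90 h of
movie remaining), where truncation cannot act. The practical reading:
effect sizes for duration estimated from movie-truncated data are
conservative, and real-data `micro` estimates inherit the same downward
pressure. MN-model inference is unaffected (MN status is scored at cycle
start, censored or not), and `scf` recovery is unbiased.

## Numerical choices and degenerate inputs

* Quantiles everywhere are empirical type-7 (linear interpolation);
  credible intervals are 25/75 and 2.5/97.5 percentiles.
* Split-R-hat rank-normalizes before computing the variance ratio and
  returns exactly 1 for numerically constant chains (0/0 guarded); a
  single chain is split in half with a warning.
* Mitotic delay uses a strict `> 2 h` comparison; a mitosis of exactly
  2.0 h is not delayed.
* Stage coding: STG = 1 for N+x (baseline 1+x).
* Cell-id path labels duplicate the topology in `parent_id`; on conflict
  `parent_id` wins and validation flags the record.
* Empty datasets are allowed in fitting (the posterior is the prior),
  which the tests use to verify the priors are proper.
* `waic()` refuses log-likelihood matrices with fewer than 2 draws or
  non-finite entries; `chisq_2x2()` refuses zero margins;
  `duration_quartiles()` needs ≥ 4 samples.
* SVG rendering writes its own `<line>`/`<rect>`/`<circle>` elements with
  `%.10g`-formatted coordinates, so identical trees always produce
  byte-identical files.

## Problem sizes used by the test suite

Recovery and model-selection checks run twenty replicate datasets at the
default study scale (~4,100–4,350 records, 300 lineages each), fitting
`1_4`, `1_2`, `2_2`, `2_2_exp` and `2_2_gamma` per replicate with 2
chains × 3000 iterations (1000 warmup; 1500/500 for the exponential and
gamma alternatives). Conjugate-oracle checks use small constructed
datasets (n = 100–400) where closed-form posteriors exist. These sizes
were chosen so each fit's Monte-Carlo error is small relative to the
posterior spread being tested.
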