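# mnlineage

Bayesian analysis of cell-lineage trees from live-cell imaging, built for
studies that follow the fate of a single defined sister chromatid fusion
(SCF). A fluorescent reporter marks cells in which a CRISPR-induced
subtelomeric rearrangement has produced one SCF; every marked cell is then
tracked through the movie, and each observed cell cycle is recorded as one
row of a tidy table (condition labels, lineage links, event flags,
durations). `mnlineage` takes such tables and answers two questions:

1. **Does a single SCF cause micronucleus (MN) formation?** The per-cycle
   MN indicator is modelled as Bernoulli with a logit link,

   `MN_n ~ Bernoulli(q_n)`, `q_n = inv_logit(b + scf·SCF_n + rnf·RNF_n +
   stg·STG_n + sis2-3·SIS_n + lin_{l(n)})`,

   where SCF / RNF / STG / SIS are experimental dummy variables and
   `lin_i` are optional per-lineage random intercepts ("lineage
   individuality", normal or Student-t).

2. **Do micronuclei destabilize the cell cycle?** Interphase duration is
   modelled as log-normal (alternatives: exponential, gamma) with
   log-median `mu_n = b + micro·MN_n + confounders (+ lin)` and a scale
   `ς` that differs among the six experimental conditions; `exp(micro)`
   is the multiplicative MN effect on the median duration.

Model structures are compared by WAIC reported on the generalization-loss
scale (nat/sample); a difference larger than 1 on the AIC scale
(`|Δ| × n × 2 > 1`) is treated as significant. Posterior-predictive MN
probabilities, fold changes, predictive duration distributions with
quartiles/IQR, Kolmogorov–Smirnov comparisons, matched sister-pair
contingency tests and deterministic SVG lineage-tree rendering complete
the pipeline. A branching-process simulator generates tidy datasets with
the same statistical structure (movie-length censoring, frame
quantization, marker fading, sporadic death/fusion events), so the whole
workflow is testable without any external data.

Posterior sampling uses an adaptive random-walk Metropolis-within-Gibbs
sampler implemented in the package (no external probabilistic-programming
dependency); lineage random intercepts are updated as one conditionally
independent block.

## Worked example

```r
library(mnlineage)

data <- simulate_lineages(sim_params(), seed = 1)  # six conditions, 300 lineages
md   <- design_matrix(data)
md
#> Model data: 4147 records, 300 lineages, 6 conditions
#>   MN events: 139 (0.034 per cycle); observed durations: 1648

fit <- fit_lineage_model(mn_model_registry()[["1_4"]], md,
                         chains = 2, iterations = 3000, warmup = 1000,
                         seed = 2)
summary(fit)
#>  parameter median   q25   q75  q2.5 q97.5 rhat ess
#>          b  -4.48 -4.59 -4.37 -4.84 -4.15    1 170
#>        scf   2.31  2.18  2.45  1.94  2.72    1 173

fc <- mn_fold_change(fit, c(SCF = 1, SIS = 1), c(), seed = 3)
#> MN probability without SCF: 0.0114; with SCF: 0.103; fold change: 9.1

waic(fit)
#> WAIC for '1_4' (n = 4147):
#>   lppd -0.12746, p_waic 0.00050, waic 0.12796 nat/sample (deviance scale 1061.261)
```

The generative values behind this dataset are `scf = 2.44` (per-cycle MN
probability 0.0102 without SCF, 0.106 with, a 10.4-fold increase) and
`micro = 0.820` (`exp(0.820) = 2.27`-fold longer median interphase with an
MN). The fitted `scf` interval covers the truth; the fitted fold change
(9.1 here) fluctuates around the generative 10.4 across simulation seeds.
Fitting the duration model `2_2` to the same data *underestimates*
`micro`: cycles still in progress at movie end are censored, and since
MN-lengthened cycles are censored far more often, the observed durations
are length-biased. See the methods vignette
(`vignettes/mnlineage-methods.Rmd`) for the full analysis of this
truncation effect.

End-to-end runs (`simulate → validate → fit → WAIC → predict → sister
pairs → trees`) are available through `run_pipeline()`; lineage trees are
drawn with `plot(tree)` or rendered to SVG with `render_tree()`.

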