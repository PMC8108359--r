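# censDA

Differential abundance (DA) analysis of cell-population count matrices
against a **right-censored covariate**, via multiple imputation inside
binomial generalized linear mixed models (GLMMs).

## The problem

Cytometry studies summarise each sample as a cluster × sample matrix of cell
population counts and ask which populations' relative abundances are
associated with a sample-level covariate. When that covariate is a survival
time, many of its values are right-censored — only a lower bound is known —
and neither treating them as observed nor discarding the incomplete samples
gives valid inference. censDA completes the censored values by multiple
imputation, analyses every completed dataset with the standard DA model, and
pools the results so the imputation uncertainty is carried into the test.

The per-cluster model is a binomial logit GLMM with an observation-level
random effect (OLRE) for overdispersion:

```
Y_j | n_j, p_j ~ Bin(n_j, p_j)
logit(p_j) = beta_0 + beta_1 T_j + beta_2 Z_j + R_j,   R_j ~ N(0, sigma^2)
```

with `T_j` the (censored) survival time and `Z_j` an optional further
covariate. Imputation strategies for censored `T`:

| method | idea |
|--------|------|
| `cc`   | complete-case analysis (listwise deletion; no MI) |
| `rs`   | uniform draw from the risk set {T_j : T_j > t} |
| `km`   | draw from the Kaplan–Meier curve of the risk set |
| `kme`  | as `km`, exponential tail for curves that do not reach zero |
| `mrl`  | add the mean residual life ∫S(u)du / S(t); needs bootstrap resampling |
| `pmm`  | predictive mean matching (ignores censoring; comparison method) |

Per-cluster results are pooled with Rubin's rules
(`T = W + (1 + 1/m) B`, Barnard–Rubin degrees of freedom) and
Benjamini–Hochberg adjusted across clusters. Two built-in simulators — the
single-cluster binomial GLMM above and a multi-cluster
Dirichlet-multinomial with associations injected through border-constrained
logit coefficients — plus metrics (raw bias, coverage, CI width, RMSE,
TPR–FDR curves) support end-to-end validation. See the vignette
(`vignettes/censored-covariate-da.Rmd`) for the methods account.

## Worked example

Simulate a 12-cluster, 100-sample study at a 30% expected censoring rate
with one compensating pair of time-associated clusters (clusters 2 and 3,
mean proportion moving between 0.05 and 0.25 across the covariate range),
then test with Kaplan–Meier imputation, m = 20 imputations:

```r
library(censDA)

cfg <- dm_config(base_alpha = default_base_alpha(12, total_concentration = 40),
                 assoc = list(list(pair = c(2, 3), pi_t0 = 0.05, pi_tmax = 0.25)),
                 n_samples = 100, censoring_rate = 0.3)
sim <- simulate_multicluster(cfg, seed = 1)
mean(!sim$metadata$event)     # realised censoring fraction: 0.26

res <- run_da(sim$counts, sim$metadata, method = "km", fixed = "z",
              m = 20, seed = 1)
head(res, 4)
```

```
   cluster_id coef  estimate       se   df statistic  p_value adj_p_value m_converged
2    cluster2 time  0.000621 6.97e-05 65.4      8.91 6.94e-13    8.32e-12          20
3    cluster3 time -0.000506 5.96e-05 49.3     -8.49 3.25e-11    1.95e-10          20
11  cluster11 time  0.000133 1.13e-04 70.6      1.18 2.43e-01    6.01e-01          20
8    cluster8 time  0.000091 8.18e-05 73.2      1.11 2.70e-01    6.01e-01          20
```

The two truly associated clusters head the table with opposite-signed
slopes of the correct magnitude (the pair is constructed to compensate:
one rises, the other falls), tiny adjusted p-values, and all 20 imputation
fits converged; every null cluster sits far above any reasonable
significance level. `estimate` is the Rubin-pooled logit-scale slope per
unit of survival time, `se` its total (within + between imputation)
standard error, and `df` the Barnard–Rubin degrees of freedom of the
pooled t test.

Count matrices and metadata round-trip through TSV with
`read_counts()` / `write_counts()` and `read_metadata()` /
`write_metadata()`; `read_metadata()` optionally applies the
`log(time + offset)` transform used for survival scales that include
non-positive values.

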