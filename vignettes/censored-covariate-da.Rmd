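---
title: "Differential abundance with a right-censored covariate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential abundance with a right-censored covariate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censDA)
```

## The problem

Differential abundance (DA) analysis in cytometry asks whether the relative
abundance of a cell population, summarised as a cluster-by-sample count
matrix, is associated with a sample-level covariate. With a binary or
continuous covariate this is routinely done by modelling each cluster's
counts with a binomial generalized linear mixed model (GLMM). Clinical
studies, however, often record a *time-to-event* covariate such as survival
time, which is right-censored: for many patients only a lower bound of the
true time is known, because follow-up ended before the event. A censored
predictor cannot simply be plugged into a regression model — treating
censored values as observed biases the coefficient towards zero, and
discarding incomplete samples wastes data and can also bias the estimate
when many samples are censored.

censDA addresses this by *multiple imputation* (MI): censored covariate
values are completed several times from their conditional distribution, each
completed dataset is analysed with the standard binomial GLMM, and the
results are pooled so that the extra uncertainty created by the imputation
is propagated into the final test.

## The model

For cluster $i$ and sample $j$, with $Y_{ij}$ cells of the cluster among
$n_j$ total cells:

$$
Y_{ij} \mid n_j, p_{ij} \sim \mathrm{Bin}(n_j, p_{ij}), \qquad
\mathrm{logit}(p_{ij}) = \beta_{0i} + \beta_{1i} T_j + \beta_{2i} Z_j + R_j,
\qquad R_j \sim N(0, \sigma^2),
$$

where $T_j$ is the (censored) survival time, $Z_j$ an optional binary
covariate, and $R_j$ an observation-level random effect (OLRE): one Gaussian
random intercept per sample, which absorbs the overdispersion relative to
the binomial that cytometry proportions always show. Additional random
intercepts (e.g. per patient when each patient contributes several samples)
can be added as independent Gaussian terms. Estimation uses the Laplace
approximation (`lme4::glmer`); the DA test is a Wald test of
$\beta_{1i} = 0$ (or of any other named coefficient), with
Benjamini–Hochberg correction across clusters.

Internally, continuous covariates are standardised before fitting and the
coefficients and covariance are mapped back exactly. This is a pure
reparameterisation — survival times on a scale of hundreds of days otherwise
produce badly conditioned Hessians.

## Handling the censored covariate

Writing $T_l$ for a value censored at $t_l$ and
$R(t_l)=\{T_j : T_j > t_l\}$ for its *risk set* (every sample with a larger
recorded time, observed or censored), the completion strategies are:

* **cc** — complete-case analysis: drop censored samples, fit once. No MI.
* **rs** — risk-set imputation: replace $t_l$ by a uniform draw from
  $R(t_l)$. The risk set is taken over *all* later times; this is the
  all-future reading of the risk-set definition (an observed-only variant
  would also be defensible; the Kaplan–Meier weighting of `km` handles the
  censored members more carefully, which is that method's point).
* **km** — Kaplan–Meier imputation: fit the Kaplan–Meier (KM) curve on
  $R(t_l)$ and draw one event time with its conditional probability mass.
* **kme** — as `km`, but when the risk-set curve does not reach zero
  (largest member censored), the residual mass is modelled by an exponential
  tail fitted by least squares to $\log S(t)$ over the last quartile of the
  curve's event times (at least two points); tail draws are shifted past the
  last event time. If a risk set contains no events at all, the tail rate
  falls back to the reciprocal mean excess time of the risk set, since a
  censored-only ML fit is degenerate.
* **mrl** — mean-residual-life imputation: deterministic, replaces $t_l$ by
  $t_l + \mathrm{mrl}(t_l)$ where
  $\mathrm{mrl}(t) = \int_t^\infty S(u)\,du / S(t)$ is the expected
  remaining time to the event, with the KM step function integrated exactly.
* **pmm** — predictive mean matching: treats censored values as missing at
  random, matches on the predicted mean of a linear model in the remaining
  covariates, and draws from the 5 nearest observed donors (the usual MI
  default). It ignores the lower-bound information in the censored value —
  imputed values may fall *below* the censored time — so it serves as a
  quasi-negative control for the censoring-aware methods.

Everywhere a KM curve must be closed (mrl, the km draw), the largest time is
treated as observed if it is censored — the standard tail convention; `kme`
exists precisely to replace that convention with a distributional tail
assumption. A censored value equal to the sample maximum has an empty risk
set and is kept as if observed. Ties between event and censoring times count
as events ($X \le C$).

## Multiple imputation and pooling

`run_mi()` runs the imputation–analysis–pooling loop for one cluster. In
classical MI each of the $m$ rounds imputes the full dataset; in the
*resampling* variant each round first draws a bootstrap sample (stratified
on the event indicator, so no bootstrap dataset is all-censored and the KM
step cannot degenerate), then imputes, then fits. Resampling is mandatory
for `mrl`: being deterministic, it would otherwise produce $m$ identical
datasets and zero between-imputation variance.

Pooling follows Rubin's rules. With per-round estimates $q_i$ and squared
standard errors $u_i$:

$$
\bar q = \tfrac1m \sum q_i, \quad
\bar W = \tfrac1m \sum u_i, \quad
B = \mathrm{Var}(q_i), \quad
T = \bar W + \left(1 + \tfrac1m\right) B,
$$

with the Barnard–Rubin small-sample degrees of freedom (bounded by the
complete-data degrees of freedom $n - p$) and a two-sided $t$ p-value for
$\bar q / \sqrt{T}$. The identity $T = \bar W + (1+1/m)B$ is asserted on
every pooled result in the test suite. The default is $m = 50$ imputations;
results stabilise around that point, and the suite checks that moving from
$m = 10$ to $m = 50$ changes the pooled estimate by less than the
between-imputation Monte-Carlo error. Per-round seeds are pre-drawn from
the master seed as a vector, so results do not depend on execution order.
Rounds whose GLMM does not converge are dropped; if fewer than 80% converge
the cluster is reported as NA rather than pooled from a biased subset.

## The simulation frameworks

### Single cluster

`simulate_single_cluster()` draws from exactly the model above for one
cluster: $n_j \sim U(10^4, 10^5)$ cells per sample, balanced binary $Z$,
defaults $\beta = (-2, -10^{-4}, 1)$ and $\sigma^2 = 1$. The survival time
is Weibull, $X \sim \mathrm{Weibull}(\lambda_t, \kappa_t)$, censored by an
independent $C \sim \mathrm{Weibull}(\lambda_c, \kappa_c)$ with
$T = \min(X, C)$. Given a target expected censoring rate, $\kappa_c$ is
solved from $P(C < X) = \int f_X(x) F_C(x) \, dx$ (adaptive quadrature split
at the scale knots, then bracketed root search on $\log \kappa_c$).

Two numerical points deserve note. First, a single quadrature over
$(0, \infty)$ silently misses the transition region of a nearly degenerate
censoring CDF (large $\kappa_c$), hence the split at the scale parameters.
Second, solving $\kappa_c$ at a *fixed* censoring scale can only reach rates
between $1 - 1/e \approx 0.632$ (the $\kappa_c \to 0$ limit, where
$F_C(x) \to 1 - 1/e$ pointwise) and $P(X > \lambda_c)$ (the
$\kappa_c \to \infty$ limit, where $C$ becomes degenerate at its scale).
No single censoring scale therefore covers a 30–70% grid;
`default_censor_scale()` picks $1.5\lambda_t$ for targets up to 60% and
$0.3\lambda_t$ above, and `solve_censoring_shape()` reports the achievable
band when asked for an unreachable rate.

The default Weibull parameters — event scale 1000, shape 1.2, in days —
emulate a clinical time-to-progression scale of roughly three years. They
are this package's choice of a realistic scenario; in applications they
should be fitted from the data at hand with `fit_weibull_censored()` (the
censoring scale from the censored arm).

### Multiple clusters

`simulate_multicluster()` generates a cluster-by-sample matrix from a
Dirichlet-multinomial (DM): $\mathbf{Y}_j \sim DM(n_j, \mathbf{A}_j)$, with
concentration parameters tied to the covariates for the associated clusters,

$$
A_{ij} = \mathrm{logit}^{-1}(\beta_{0i} + \beta_{1i} T_j + \beta_{2i} Z_j)
\; A_{\bullet j},
$$

where $A_{\bullet j}$ is the per-sample concentration total. The $\beta$'s
are solved from border constraints in closed form
(`solve_association_betas()`): the mean proportion at $T = 0$ gives
$\beta_0$, the mean proportion at $T = t_\mathrm{max}$ gives $\beta_1$, and
a mean-abundance difference at $T = 0$ gives $\beta_2$. Because the
concentration total depends on all clusters, associated clusters are
injected in *compensating pairs* of similar baseline proportion with
mirrored constraints, so the total is exactly conserved at the two borders
and drifts only slightly in between (the suite asserts < 5% relative drift;
in the default scenarios it is ~0.5%). All concentrations are multiplied by
5 — preserving every expected proportion while damping the across-sample
spread of proportions toward what real cytometry data show. Sampling is by
Gamma-normalised Dirichlet proportions followed by a multinomial draw.
$t_\mathrm{max}$ defaults to the 99.5% quantile of the event distribution.

Baseline concentrations would in practice be fitted from a real count
matrix with `fit_dirichlet_multinomial()` (a fixed-point ML iteration on
the DM likelihood); the shipped default (`default_base_alpha()`: 20 clusters
with geometrically decaying proportions, total concentration 30) is a
plausible synthetic stand-in, not parameters from any particular dataset.
The scenario grid of interest crosses sample sizes 50/100/200/400 with
censoring rates 30/50/70%.

### Truth labels and evaluation

The simulator records per cluster whether $\beta_{1i} \ne 0$
(time-associated) and $\beta_{2i} \ne 0$ (Z-associated). `compute_metrics()`
summarises replicated estimates by raw bias, coverage rate of the 95% CI,
mean CI width and RMSE (on the squared scale,
$\mathrm{MSE} = \mathrm{Var} + \mathrm{Bias}^2$, an identity the tests
assert). `tpr_fdr()` computes TPR–FDR operating points at thresholds 0.01,
0.05 and 0.1, with the convention $\mathrm{FDR} = FP / \max(1, \text{
discoveries})$ so an empty discovery set scores zero.

## What the tests do and do not show

The check suite runs scaled-down versions of the validation studies: 95% CI
coverage of $\beta_1$ under `km` imputation (50 replicates of the n = 100,
30%-censoring scenario at $m = 10$), unbiasedness of complete-case
estimation (100 replicates), uniformity of null p-values (1000 replicates,
Kolmogorov–Smirnov against U(0,1) at the 1% critical value), empirical
censoring rates against the solved shapes at $10^5$ draws, and the
global-null DA workflow on a 20-cluster, 50-sample DM scenario. These sizes
keep the default run in the minutes range on one CPU; they are Monte-Carlo
checks with binomial tolerances, not exact reproductions of any larger
study.

The simulations assume censoring completely at random (the censoring time is
independent of everything else), a correctly specified logit-linear mean,
and Weibull margins. Real cytometry data can violate all three — most
importantly, censoring that depends on covariates (informative censoring)
is *not* modelled: covariate-dependent risk sets in the style of Hsu et al.
are not implemented, and complete-case analysis in particular is known to
be biased away from the MCAR setting. Passing tests validate the
machinery under these stated conditions; they do not certify error control
on data whose censoring mechanism is informative.

## Known limitations

* Right censoring only; no left/interval censoring, competing risks or
  time-varying covariates.
* Laplace approximation only (no adaptive quadrature); no REML.
* `pmm` deliberately ignores the censoring lower bound (that is its role as
  a comparison method).
* MI is computationally heavy: a DA run costs
  clusters × m GLMM fits. The per-cluster loop is embarrassingly parallel if
  needed; the implementation keeps it sequential and deterministic.
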