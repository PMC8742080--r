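---
title: "Joint species distribution modelling of zero-inflated survey abundance"
author: "jsdmTobit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint species distribution modelling of zero-inflated survey abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Bottom-trawl surveys record catch per unit effort (CPUE, kg/tow) for many
species at once. The data are continuous with a large point mass at zero:
a species is absent from most tows and, when present, contributes a
positive biomass. Fitting each species separately (a single-species
distribution model) ignores that all species come from the same tows and
co-vary beyond what the environment explains.

`jsdmTobit` models the whole community jointly. For tow $i$ and species
$s$, a latent Gaussian variable $w_{is}$ drives the observation:

$$
y_{is} = \begin{cases} w_{is} & w_{is} > 0 \\ 0 & w_{is} \le 0,\end{cases}
\qquad
\mathbf{w}_i \mid \mathbf{x}_i \sim \mathrm{MVN}(\mathbf{B}'\mathbf{x}_i,\ \Sigma)
$$

This is the multivariate tobit: the length-$S$ latent vector is
multivariate normal with a mean structure driven by the $Q$ design
covariates (coefficients $\mathbf{B}$, $Q \times S$) and a full $S \times
S$ residual covariance $\Sigma$. Presence/absence data use the same latent
model with $y_{is} = \mathbf{1}(w_{is} > 0)$ — the multivariate probit —
in which case only the correlation matrix of $\Sigma$ is identified.

Derived quantities reported by the package:

* **Residual correlation** $R_{ss'} = \Sigma_{ss'} / \sqrt{\Sigma_{ss}\Sigma_{s's'}}$ —
  species co-dependence left after the environmental mean structure;
  interpretable as missing covariates, model misspecification, or biotic
  interaction, and exploitable for conditional prediction.
* **Community sensitivity** $f = \mathrm{diag}(\mathbf{B}\Sigma^{-1}\mathbf{B}')$ —
  a length-$Q$ nonnegative score of how strongly each design column drives
  the entire response matrix.
* **Environmental covariance** $E = \mathbf{B}'V\mathbf{B}$ — species
  similarity induced by shared environmental responses, weighted by the
  predictor covariance $V$ (taken from the observed design,
  `predictorCovariance()`, intercept zeroed).
* **Variance partition** — per species, the share of total response
  variance, $\mathrm{Var}_i(\mu_{is}) + \Sigma_{ss}$, that comes from the
  mean structure.

## Fitting

`fitJsdm()` runs a Gibbs sampler over three exact conditional updates:

1. **Latent matrix.** Censored entries are drawn from their univariate
   conditional normal given the other species in the row, truncated to the
   censoring region, sweeping species in fixed column order. Positive CPUE
   entries are held at the observed value exactly. Truncated draws use the
   inverse-CDF method evaluated in log space, so the quantile stays finite
   when the conditional mean lies far from the truncation bound.
2. **Coefficients.** Under a flat prior, a matrix-normal draw with mean
   $(X'X)^{-1}X'W$, row covariance $(X'X)^{-1}$, column covariance $\Sigma$.
3. **Covariance.** Inverse-Wishart with shape $\nu_0 + n$ and scale
   $\Psi_0 + (W - XB)'(W - XB)$.

Priors are deliberately weak: flat on $\mathbf{B}$ and
$\mathrm{IW}(\nu_0 = S + 2,\ \Psi_0 = I_S)$ on $\Sigma$ — proper and
conjugate, with prior weight equivalent to a single observation per
species, so the data dominate. For presence/absence the chain samples an
unrestricted $\Sigma$ and rescales every stored draw to a correlation
matrix with $B_{qs} \leftarrow B_{qs}/\sqrt{\Sigma_{ss}}$ (parameter
expansion), the standard identification for the multivariate probit.

Latent states start from a feasible point ($y$ for positive CPUE, $-0.5$
for censored entries, $\pm 0.5$ by label for presence/absence). Default
chain lengths are 20,000 iterations with 8,000 burn-in for a final fit;
selection stages use 5,000/800, and exhaustive grids 1,000/400. A single
run seed deterministically spawns all sub-streams, so identical inputs
reproduce identical draws. Species columns with no nonzero observation are
rejected at fit time — they carry no information about their coefficients
or covariances; `filterSpecies()` implements the survey inclusion rule
(present in at least 400 tows and at least 0.5 kg/tow in more than 100
tows, thresholds configurable).

Design matrices standardize continuous covariates (mean 0, sd 1) before
interaction columns are formed, and record the transform so prediction
designs replay it exactly; factors use treatment coding against the first
declared level (e.g. subregion against Gulf of Maine).

## Prediction and conditional prediction

`predictJsdm()` propagates posterior draws through the latent model and
censors to the observation scale, giving predictive means and 90/95%
intervals; presence/absence means are occurrence probabilities.
`conditionalPredict()` uses the multivariate-normal partition on the
latent scale: conditioned species' latents are fixed at observed CPUE when
positive and sampled from the censored region otherwise; targets follow
$\mathrm{MVN}(\mu_T + \Sigma_{TC}\Sigma_{CC}^{-1}(w_C - \mu_C),\
\Sigma_{TT} - \Sigma_{TC}\Sigma_{CC}^{-1}\Sigma_{CT})$. With nothing
conditioned on it reduces to the marginal prediction path, same seed and
all.

## Inverse prediction

Inverse prediction asks how well the community predicts the environment
through the fitted model: a covariate the community cannot predict does
not explain important variation in any species. For each posterior draw
and observation row, the package maximizes the censored-data
log-likelihood of the observed response row over the free covariate (on
the standardized scale, bounded at $\pm 4$), recomputing any interaction
columns from the trial value and holding all other covariates at their
observed values. The objective treats positive entries exactly (MVN
density on that block) and censored entries through their conditional
censoring probabilities given the positive block, taken independent of
one another given the positives.

This objective was a genuinely open design point. An alternative is to
impute the censored latent entries from their conditional distribution at
the observed covariates and then maximize the full-row Gaussian
likelihood. We rejected it because the imputation is anchored at the
observed covariate row: for a factor, censored entries then systematically
favour the observed level, so a covariate with no true effect still
scores well above chance at any sample size, which defeats the purpose of
the score. The censored-likelihood objective is leak-free, deterministic
given the draws, and for a fully positive row coincides with the
generalized-least-squares closed form
$\hat x = (b\Sigma^{-1}b')^{-1} b\Sigma^{-1}(w - \mu_{-})$, which the test
suite verifies to $10^{-6}$. Factor inversion evaluates the same
likelihood at each declared level and normalizes. Interactions are never
treated as free columns — they are deterministic functions of their
parents, and freeing them would allow infeasible covariate combinations.

## Variable selection

Two workflows are provided.

**Sensitivity + inverse prediction** (`selectByInversePrediction()`): fit
the saturated model, compute the posterior of the sensitivity vector and
per-covariate inverse-prediction scores, and drop every term that both
contributes little sensitivity (posterior median below 10% of the largest
term's) and belongs to a covariate the community cannot predict
(inverse $R^2 < 0.1$ for continuous; accuracy below chance $+ 0.05$ for
factors); refit and repeat. Interactions drop before their main effects —
a main effect survives while any interaction containing it does. The
thresholds formalize what is otherwise a visual judgement on sensitivity
and inverse-prediction panels; they are configurable.

**Exhaustive grid** (`selectByGrid()`): enumerate all $2^{|\text{optional}|}$
candidates over the optional terms (`enumerateModelGrid()`; candidates may
contain an interaction without its parent main effect, since screening
grids treat depth interactions as independent switches), train each on a
70% split, shortlist the ten lowest in-sample DIC models, and pick the
best pooled out-of-sample $R^2$. We read the selection direction as the
highest out-of-sample $R^2$ — selecting the worst predictor would be
incoherent — and expose it as a flag. Train size is `fraction * n` rounded
half-up, so a 70% split of 5,935 tows is 4,155/1,780 and of 5,217 tows is
3,652/1,565.

DIC uses the complete-data (conditional) form for latent-variable models:
$\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, with the
deviance $-2\log \mathrm{MVN}(W; XB, \Sigma)$ accumulated over retained
draws during sampling and evaluated once at the posterior means.

## The synthetic survey generator

`generateCovariates()` draws correlated environmental covariates
(bottom/surface temperature and salinity, depth) from a multivariate
normal on realistic scales — depth 10–300 m, temperatures 3–27 °C,
salinities around 31–35 psu, corr(depth, BT) = −0.5 — with a two-level
subregion factor that shifts covariate means (the southern region warmer
and shallower) and places tows in region-specific coordinate boxes. The
model consumes standardized values, so the scales are cosmetic defaults
chosen for readable fixtures. `generateCommunity()` runs the latent model
generatively and censors, returning the latent matrix alongside the
observations so tests can verify censoring exactly.
`defaultNeusScenario()` assembles a shelf-scale survey: 5,217 tows by 30
species under the final-model mean structure (intercept, BT, depth, BSAL,
SST, subregion, and three depth interactions; $Q = 9$), two species
clusters with opposite-sign temperature responses, block-structured
residual correlation (0.4 within, −0.15 between), and one rare species
with an intercept at $\Phi^{-1}(0.10)$ so that roughly 10% of its rows are
nonzero, emulating the rarest species retained by the survey filters.

What the generator does **not** emulate: spatial and temporal residual
autocorrelation (tows are exchangeable given covariates), gear and vessel
effects, stratified allocation, measurement error in covariates, and
non-Gaussian residual tails. Passing tests on these data therefore
validate the estimator and its calibration under the stated model, not
robustness to the survey artefacts real data carry; the semivariogram and
PACF diagnostics exist precisely to check the exchangeability assumption
on real residuals.

## Numerical choices and problem sizes

* Truncated-normal draws: inverse CDF in log space; results are clamped to
  the truncation bound to guarantee the censoring invariant bit-exactly.
* Conditional variances in the latent sweep are floored at $10^{-12}$;
  conditional covariances in prediction get a $10^{-10}$ diagonal jitter
  only if an eigenvalue falls below $10^{-12}$.
* Rank deficiency of the design is detected by pivoted QR and reported
  with the offending columns; zero-variance covariates are rejected before
  standardization.
* k-means aggregation (`aggregateByKmeans()`, default $k = 50$) retries
  with fresh seeds on empty clusters, and $k = n$ is the identity
  aggregation. The semivariogram uses haversine distances with ten
  equal-width bins up to the median pairwise distance by default; the PACF
  uses the Durbin–Levinson recursion with lag 0 defined as 1. Precision at
  thresholds predicting no presences is skipped as undefined (0/0), not
  imputed, over the 101-point grid $0, 0.01, \ldots, 1$.
* The validation suite runs at reduced but informative sizes chosen to
  exercise the asymptotics that matter: oracle equivalence at $n = 1000,
  S = 5$; calibration at $n = 2000, S = 10, Q = 5$ over five replicate
  chains of 4,000 iterations; selection power over twenty replicates of
  4-candidate grids at $n = 150$ (grid workflow, where small samples make
  the overfitting penalty visible out of sample) and $n = 400$ (pruning
  workflow). The same quantities are recomputed end to end by
  `scripts/acceptance.R`.

## Known limitations

* Full $S \times S$ covariance sampling only; no latent-factor
  approximation, so fits beyond roughly 40 species get slow and
  memory-hungry.
* No spatial or temporal random effects; residual structure is diagnosed
  (`residualSemivariogram()`, `residualPacf()`) but not modelled.
* Inverse prediction's censored-entry treatment assumes conditional
  independence of censored species given the positive ones; with many
  strongly correlated absent species the scores are approximate.
* The probit branch identifies only the correlation matrix; magnitudes of
  presence/absence coefficients are on the unit-variance latent scale.
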