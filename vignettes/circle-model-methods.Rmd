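---
title: "Concentric circle models of grooming networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentric circle models of grooming networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(groomcircles)
library(dplyr)
```

## The model

Many social animals do not spread their affiliative effort evenly: a few
partners receive intense investment and a growing number receive less,
forming concentric "circles" around each individual. `groomcircles`
quantifies this layering for grooming networks with a one-parameter
maximum-entropy model of how an ego distributes a finite social budget.

### Discrete layers

With `r` relationship categories of strictly decreasing cost
$s_1 > \dots > s_r$, the maximum-entropy probability that a tie falls in
category $k$ is a Boltzmann weighting
$p_k = Z_r^{-1} e^{-\hat\mu s_k}$ (`discrete_layer_probs()`). Writing
$\mu = \hat\mu (s_{\max}-s_{\min})/(r-1)$, the expected cumulative fraction
of ties in the innermost $k$ circles is
$\chi_k = (e^{k\mu}-1)/(e^{r\mu}-1)$ (`chi_discrete()`), and for large
$\mu$ consecutive circles grow by the *scaling ratio* $e^\mu$ — the ratio
near 3 repeatedly reported for human ego-networks. Negative $\mu$ yields
the *inverted* regime: almost all ties in the innermost circle.

### Continuous parameter $\eta$

The continuous analogue replaces categories with a normalized distance
$t_i = (s_{\max}-s_i)/(s_{\max}-s_{\min}) \in [0,1]$ per tie ($t=0$
strongest, $t=1$ weakest; `normalize_distances()`). The cumulative tie
fraction is $\chi(t) = (e^{\eta t}-1)/(e^\eta-1)$ and the mean distance
satisfies the implicit equation

$$\bar t \;=\; \frac{e^\eta}{e^\eta-1}-\frac{1}{\eta},$$

which `solve_eta()` inverts. The two formalisms are linked by
$\eta \approx (r-1)(e^\mu-1)$: with the conventional $r = 4$ layers and
ratio $e^\mu \approx 3$, $\eta \approx 6$ (`eta_from_mu(log(3), 4)`).
$\eta > 0$ is the normal concentric regime, $\eta < 0$ the inverted one.

### Likelihood and confidence intervals

Treating $\chi(t)$ as a CDF gives the truncated-exponential density
$f(t;\eta) = \eta e^{\eta t}/(e^\eta-1)$ on $[0,1]$. Its log-likelihood
$\ell(\eta) = L\log|\eta| + \eta\sum_i t_i - L\log|e^\eta-1|$ is strictly
concave, and its stationarity condition is exactly the implicit mean
equation — so the bisection solution *is* the maximum-likelihood estimate.
The test suite verifies this equivalence against a generic numerical
maximizer on hundreds of simulated egos.

Confidence intervals invert the likelihood-ratio statistic: the
$1-2\delta$ interval is $\{\eta: 2[\ell(\hat\eta)-\ell(\eta)] \le
\chi^2_1(1-2\delta)\}$, with $\delta = 0.025$ (95%) by default. A closed
form exists in the literature for this family but is not reproduced here;
the likelihood-ratio interval is asymptotically equivalent, and its
empirical coverage at $L = 200$ is verified by simulation to sit inside
[0.92, 0.98].

## A worked example

```{r}
fit <- fit_ego(c(1, 1, 10))
fit
```

One strong partner (weight 10) and two weak ones gives $\bar t = 2/3$ and
$\hat\eta \approx 2.15$: a normal, concentric ego-network, though with
only three ties the interval is wide.

## Input conventions and filters

Interaction records are directed dyadic aggregates (`group_id, actor_id,
receiver_id, weight`); mutual grooming is two records, one per direction.
An ego's distribution is its **outgoing** grooming (how it allocates
effort), with received grooming available via `direction = "in"` as a
sensitivity check. Weights may be counts or durations — the model only
requires positive values. Zero-weight dyads are absent partners, never
$t = 1$ ties.

The standard inclusion filters (`apply_filters()`) drop groups with fewer
than 6 individuals and egos that groomed fewer than 5 distinct partners;
group size is demographic (inactive individuals count toward size).
Egos whose ties all have identical weight are excluded as degenerate —
$s_{\max} = s_{\min}$ leaves $\eta$ undefined — and every exclusion is
recorded with a reason in the audit table.

### Choice of weight bounds

By default $s_{\max}$ and $s_{\min}$ are each ego's own largest and
smallest tie weight, so every ego has one tie at $t=0$ and one at $t=1$.
This is the natural choice for observational data, where the feasible
weight range is unknown. Its cost is a finite-sample attenuation: with
$L$ ties the observed extremes under-cover the theoretical range, which
pulls large $|\hat\eta|$ toward zero (noticeably for $|\eta| \ge 6$ at
$L \lesssim 100$). When the generating scale is known — as for synthetic
cohorts — dataset-wide bounds can be supplied (`s_max`, `s_min` arguments
of `fit_ego()`/`fit_egos()`), which removes the attenuation; the
parameter-recovery checks use this mode.

## Numerical choices

- `mean_distance_curve()` evaluates $1/(1-e^{-\eta}) - 1/\eta$ for
  $\eta > 0$ and uses the antisymmetry $g(-\eta) = 1-g(\eta)$ for
  $\eta < 0$; for $|\eta| < 10^{-2}$ the series
  $1/2 + \eta/12 - \eta^3/720$ is used (truncation error under
  $4\times10^{-15}$, versus catastrophic cancellation in the closed form).
- `solve_eta()` brackets in $[-700, 700]$ (widened automatically for
  $\bar t$ extremely near 0 or 1) with tolerance $10^{-9}$; within
  $10^{-6}$ of $\bar t = 1/2$ the series inverse
  $\eta \approx 12(\bar t - 1/2)$ avoids the removable singularity.
- $\chi$, its log-derivative and the likelihood are computed with
  `expm1`/`log1p` forms that stay finite for $|\eta|$ up to several
  hundred.
- Interval endpoints are found by outward doubling then `uniroot`;
  the search fails loudly beyond $\hat\eta \pm 100$.
- $\chi_k$ at $\mu = 0$ and $\chi(t)$ at $\eta = 0$ use their uniform
  limits $k/r$ and $t$.

## Group structure: modularity

Directed grooming graphs are symmetrized by summing the two directions,
and weighted Newman modularity $Q = \sum_c (e_{cc} - a_c^2)$ is computed
on the result (binarizing would discard the resource-allocation signal).
Because no single heuristic is reliable on small dense graphs,
`detect_communities()` runs a seeded portfolio — greedy agglomeration,
multilevel (Louvain) and leading eigenvector — and keeps the partition
with the highest $Q$. Tests check the portfolio against exhaustive
enumeration of all partitions on graphs of up to 8 vertices, and
`group_structure_table()` pairs each group's $Q$ with its mean
$\hat\eta$: cohorts in which grooming is more concentrated should, and in
simulation do, segment into more modular societies.

## The synthetic cohort generator

`generate_cohort()` emulates a captive *Pan* study population at the level
the estimator consumes: groups of configurable size (minimum 6), an
ego-network size $L$ per individual drawn uniformly (minimum 5, so
generated cohorts pass the inclusion filters by construction), and per-ego
$\eta$ built from a linear predictor over species, sex, standardized age,
habitat, ego-network size, group size and the species-by-age and
species-by-sex interactions, plus Gaussian noise. Tie distances are drawn
by inverse-CDF sampling from $\chi$ and mapped onto a weight scale
(default 1–50), optionally rounded to integer counts with floor 1.

Defaults were fixed once at values plausible for such a population:
intercept 2 with a dominant ego-size coefficient 0.15 and a negative
species-by-age interaction (−0.3 per SD of age) as the planted analogues
of the effects the attribution stage should detect; noise SD 0.5; sex
ratio 36% male; ages uniform on 5–45 years. An optional two-block
structure biases partner choice within blocks (configurable odds ratio)
to plant community structure for modularity experiments.

The generator reproduces the model's own data-generating process. It does
**not** simulate the observation process — scan-sampling intervals,
visibility bias, observer error — nor temporal dynamics or reciprocity
beyond what random partner assignment produces. Passing recovery tests
therefore show the estimator and attribution machinery are correct and
calibrated under the model, not that field data satisfy the model.

## Covariate attribution

`fit_attribution_model()` fits gradient-boosted regression trees
(xgboost; squared-error loss) predicting $\hat\eta$ from the eight
predictor columns. The model is explanatory, so it is fit on the full
table — no held-out split — with hyperparameters fixed at shallow trees
(depth 3), 300 rounds, learning rate 0.1, single-threaded for
determinism. Global importance is normalized total split gain.
`shap_attributions()` uses exact TreeSHAP, whose local accuracy
(base value + attributions = prediction) holds on every row up to
float32 summation error (observed below $10^{-5}$; asserted below
$10^{-4}$). `partial_dependence()` conditions all other numeric features
at their median and indicators at their mode — single-point conditioning,
which is jagged for tree ensembles; an averaged classical PDP is
available with `average = TRUE`.

## Problem sizes used in validation

The simulation-based checks use: 200 egos for the estimator-vs-likelihood
equivalence; 1000 egos of $L = 200$ ties for CI coverage; 200 replicates
of $L = 500$ per planted $\eta \in \{-6,-2,0,2,6\}$ for bias; a ~400-ego
cohort with $L \in [50, 200]$ for pipeline-level slope recovery; and 20
replicate cohorts each for the $\eta$–modularity association (6 groups of
16, planted group means $\{0.5, 3, 6\}$, block odds $1+2\eta$) and for
attribution recovery (8 groups of 42–48, $L \in [10, 40]$). These sizes
give the stochastic checks comfortable margins while keeping the full
suite at a few minutes on one core.

## Known limitations

- Per-ego bounds attenuate extreme $|\eta|$ at small $L$ (quantified
  above); cross-individual comparisons at very different $L$ inherit a
  small differential bias.
- The likelihood treats ties as i.i.d. draws given $\eta$; reciprocity
  and partner-identity structure are ignored by design.
- Community detection on very small groups (6–10 members) is noisy, and
  modularity values across groups of different size are not strictly
  comparable.
- Boosted-tree importance and Shapley values attribute associations, not
  causal effects; correlated covariates share credit.
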