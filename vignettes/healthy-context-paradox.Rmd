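---
title: "Testing the healthy context paradox in cluster-randomised trials"
author: "hcptest authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the healthy context paradox in cluster-randomised trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcptest)
```

## The problem

A cluster-allocated intervention (say, a whole-school anti-bullying
programme) that reduces an adverse mediator on average can simultaneously
worsen outcomes for the individuals in whom the mediator persists: as
victimisation becomes rarer, remaining victims may be more isolated and
suffer a larger wellbeing decrement. This "healthy context paradox" is a
moderation phenomenon: the intervention changes not (only) the level of the
mediator but the *strength of the mediator-outcome association*. Because a
mediator measured on individuals aggregates to cluster means, that
association exists at two levels — within clusters (individual effect) and
between clusters (contextual effect) — and the paradox can operate at
either. It is only detectable when treatment is allocated at the cluster
level, since an individually randomised design provides no contrast between
cluster-level and individual-level mediator effects.

`hcptest` frames this as a 2-1-1 multilevel mediation model (treatment at
level 2; mediator and outcome at level 1) plus two moderation tests, one
per level.

## Models

Let $T_j \in \{0, 1\}$ be the arm of cluster $j$, $m_{ij}$ and $y_{ij}$ the
mediator and outcome of individual $i$, and $\bar M_j$ the observed cluster
mean of the mediator.

**Baseline (uncentred formulation).** Two Gaussian random-intercept models
estimated by full maximum likelihood:

$$m_{ij} = \alpha_0 + a T_j + u^M_j + e^M_{ij}$$
$$y_{ij} = \beta_0 + b_w m_{ij} + b_b \bar M_j + c' T_j + u^Y_j + e^Y_{ij}$$

With the *uncentred* individual mediator alongside its cluster mean, the
cluster-mean coefficient $b_b$ is the contextual effect — the difference
between the between-cluster and within-cluster slopes — while $b_w$ is the
within (individual) slope. Indirect effects are $a b_w$ (within),
$a b_b$ (contextual) and $a(b_w + b_b)$ (total); the total is computed as
the literal floating-point sum of the two components, so additivity is
exact in every fit. A non-significant $a$ fails the mediator screen: the
package warns that the candidate mediator should not be pursued, but never
refuses to run the moderation tests — a null mediator-outcome association
at one level can be the misleading average of opposing effects at the two
levels.

**Test 1 (contextual).** The outcome equation gains the product
$T_j \times \bar M_j$ with coefficient $\gamma_B$, letting the contextual
slope differ by arm. The comparison against the baseline is a Wald test on
the single constrained parameter (df = 1).

**Test 2 (individual).** The mediator is cluster-mean centred
($\tilde m_{ij} = m_{ij} - \bar M_j$) and receives a cluster random slope
$s_j$ with variance $\tau^2_1$ and covariance $\tau_{01}$ with the random
intercept; the slope's regression on treatment is the fixed product term
$T_j \times \tilde m_{ij}$ with coefficient $d$ (the standard
random-coefficients representation). The deviation's main coefficient is
then the control-arm within slope, and the cluster-mean coefficient no
longer estimates the contextual effect alone but approximately
$b_w + b_b$, the sum of the individual and contextual effects — a property
the test suite verifies on a large simulated trial. Two Wald comparisons
are reported, both computed from the full fit's joint parameter
covariance: against the baseline, constraining $(d, \tau^2_1, \tau_{01})$
(df = 3); and against the reduced model retaining only the random slope,
constraining $(d, \tau_{01})$ (df = 2). We define the baseline here as
having no random-slope structure at all, which is what yields those
degrees of freedom.

**Direction rule.** With the default scale orientations (higher mediator =
worse, e.g. victimisation; higher outcome = better, e.g. wellbeing) the
adverse mediator-outcome association is negative, so a paradox — a
*stronger* adverse association under intervention — appears as a
*negative* significant moderation at either level. `classify_hcp()`
returns `paradox_supported`, `opposite_direction` or `not_supported`
accordingly; flipping either direction flag flips the expected sign.

## Estimation

The two tests need Wald statistics that jointly constrain a fixed effect
and variance components, hence a parameter covariance spanning both. The
package therefore fits its mixed models with its own ML engine:

- The marginal likelihood is evaluated per cluster through the Woodbury
  identity on the $q \le 2$-dimensional random-effects structure,
  vectorised across clusters over pre-computed sufficient statistics, so an
  evaluation costs $O(J)$ regardless of the number of individuals.
- $\beta$ (GLS) and $\sigma^2$ are profiled out in closed form; the
  remaining variance *ratios* are optimised on an unconstrained
  log-Cholesky scale, so every iterate maps to a valid covariance matrix.
- The profiled likelihood is flat in $\log(\tau_0/\sigma)$ as
  $\tau_0 \to 0$, which can strand gradient methods started on the steep
  side. The intercept ratio is therefore located by a coarse grid plus
  golden-section refinement; slope models start from that solution and
  refine by Nelder-Mead followed by BFGS. Convergence is declared from the
  relative gradient norm on the unconstrained scale (where a boundary
  optimum genuinely has zero slope), with the thresholds configurable via
  `lmm_control()`.
- The parameter covariance is the inverse observed information: a central
  finite-difference Hessian of the unprofiled likelihood on the natural
  scale $(\beta, \sigma^2, \tau^2_0, \tau^2_1, \tau_{01})$. Near the
  $\tau^2_1 = 0$ boundary the likelihood continues smoothly to slightly
  negative values (the Woodbury form stays finite), so the differences are
  well defined; when the information matrix has a non-positive direction —
  the signature of a boundary fit — eigenvalue magnitudes are kept
  (absolute values with a relative floor), the covariance is flagged, and
  Wald results that touch variance components carry an explicit caveat
  that the chi-square reference is non-standard on the boundary. ML (not
  REML) is used throughout so that comparisons across fixed-effect changes
  remain coherent.

Correctness of the engine is established two independent ways in the test
suite: fitted log-likelihoods agree to $10^{-6}$ with a dense stacked
multivariate-normal evaluation on small instances, and estimates,
log-likelihoods and variance components agree with `lme4::lmer(REML =
FALSE)` on larger ones.

### Small-sample inference

Single-coefficient p-values default to a t reference with between-within
denominator degrees of freedom (the HLM/nlme convention): cluster-level
terms use $J - p_B$, random-slope-model terms (the deviation and its
treatment product) use $J - p_S$, and purely within terms use
$N - J - p_W$. Reported standard errors additionally carry the matching
REML-style rescaling $\sqrt{m/(m - p)}$ at the term's level, compensating
the downward bias of ML variance components (ML divides by the number of
level-$m$ units, not units minus estimated coefficients). With ~40
clusters, plain normal-reference Wald z tests on cluster-level terms are
visibly anti-conservative (empirical size ~0.075 at nominal 0.05 in our
null simulations); with both corrections the two moderation tests hold
their size within Monte-Carlo error, which the acceptance suite verifies
at 1000 replicates. `df_method = "normal"` restores uncorrected Wald z
inference for comparison. Multi-parameter model comparisons remain plain
observed-information chi-square Wald tests, matching how such comparisons
are conventionally reported.

The indirect-effect uncertainty treats $\hat a$ and $(\hat b_w, \hat b_b)$
as independent because they come from two separately fitted equations;
under correctly specified Gaussian models the paths are asymptotically
uncorrelated, so this is a documented approximation rather than an exact
joint fit. Both a first-order delta-method interval and a seeded
Monte-Carlo percentile interval (default 10,000 draws from the joint
normal approximation) are reported; the suite checks that they agree to
within 10% of the interval width on a large trial.

## The synthetic trial generator

`trial_scenario()` encodes the generative model

$$\mu_{Mj} = \alpha_0 + a T_j + u^M_j, \qquad m_{ij} = \mu_{Mj} + e^M_{ij}$$
$$y_{ij} = \beta_0 + c' T_j + (b_b + b_w + \gamma_B T_j)\,\mu_{Mj}
  + (b_w + d T_j + s_j)(m_{ij} - \mu_{Mj}) + u^Y_j + e^Y_{ij}$$

with $(u^Y_j, s_j)$ jointly normal. The defaults describe the kind of
trial that motivates the package: $J = 40$ schools of $n_j = 150$
students, mediator on a victimisation-type scale (higher = worse),
wellbeing outcome (higher = better), $b_w = -0.687$, $b_b = 0.34$,
$\gamma_B = d = 0$. Variances ($\tau^2_M = 0.05$, $\sigma^2_M = 0.5$,
$\tau^2_0 = 0.4$, $\tau^2_1 = 0.02$, $\sigma^2 = 9$) were chosen once so
that the standard errors of $b_w$ (~0.06) and $b_b$ (~0.46) at the default
sizes match the order of magnitude reported for trials of this scale; the
treatment-mediator effect $a = -0.30$ is a package choice, as no reference
value is available for it. The planted-effect presets
(`scenario_contextual_paradox()`, $\gamma_B = -2.5$;
`scenario_individual_paradox()`, $d = -0.6$) are sized by the analytic
standard errors at trial scale to give roughly 80% power or more.

Two deliberate features deserve note. Generation conditions on the
*latent* cluster mean $\mu_{Mj}$ so that generating parameters have clean
within/between interpretations, while estimation uses the *observed* mean
$\bar M_j$; the measurement-error gap $\sigma^2_M / n_j$ attenuates
between-level coefficients by a factor
$\tau^2_M / (\tau^2_M + \sigma^2_M/n_j)$ (~6% at $n_j = 150$), which is
well inside Monte-Carlo error at the replication sizes used but would
matter for very small clusters. And under null moderation with
$\tau^2_1 = 0$ the outcome's intraclass correlation has the closed form

$$\mathrm{ICC} = \frac{(b_b + b_w)^2 \tau^2_M + \tau^2_0}
  {(b_b + b_w)^2 \tau^2_M + \tau^2_0 + (b_w^2 + \tau^2_1)\sigma^2_M + \sigma^2},$$

which the test suite checks against a moment estimator on a large sample —
a guard that the generative equations mean what they claim.

What the generator does *not* emulate: attrition and missingness,
covariates, non-normal or bounded scales, unequal allocation beyond a
treated fraction, and three-level structure. Passing tests therefore
demonstrate the statistical machinery under idealised Gaussian conditions,
not robustness to the messiness of real trial data.

## Monte-Carlo studies and problem sizes

`operating_characteristics()` runs generate → Test 1 → Test 2 per
replicate, with replicate $r$ seeded `base_seed + r` so any single
replicate is reproducible in isolation; non-converged fits are excluded
from denominators and counted (a warning fires above 20% failures;
rejection is $p \le \alpha$, so $\alpha = 1$ rejects every replicate by
construction). The shipped studies use 1000 replicates at $n_j = 50$ for
type-I error (both tests hold $[0.03, 0.07]$ at nominal 0.05) and 150
replicates at full trial size for the planted-effect power checks; those
sizes give Monte-Carlo standard errors below 0.008 and 0.04 respectively
while keeping a full run in a few minutes on one CPU.

## Design choices and open points

- **Missing data**: listwise deletion on the analysis variables with a
  logged count; anything more principled is out of scope.
- **Treatment coding**: any two-valued column is recoded 0/1 with an
  explicit, logged mapping (first sorted level = control), which keeps the
  moderation sign rule interpretable.
- **Manifest cluster means**: the between-level predictors are observed
  means of retained records, not latent/model-implied means; latent-mean
  decomposition is deliberately out of scope.
- **Boundary Wald tests**: comparisons constraining $\tau^2_1$ or
  $\tau_{01}$ use the plain chi-square reference (as such comparisons are
  conventionally printed) and always carry the boundary caveat, since the
  usual mixture asymptotics would be more conservative.
- **Screening never gates**: a failed treatment-mediator screen is a
  prominent warning, never a refusal.
- Non-normal mediators or outcomes, survey weights, multiple mediators,
  moderated mediation by an external fourth variable, and crossed random
  effects are out of scope.
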