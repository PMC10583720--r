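---
title: "Cross direct effects with two binary mediators: models, bounds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross direct effects with two binary mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A randomized binary exposure $X$ (say, vaccination) acts on a binary outcome
$Y$ (disease) partly through two binary mediators $M_1$ and $M_2$ (say, a
memory B-cell response and circulating antibody). Beyond the familiar
controlled direct effect (both mediators fixed for everyone) and natural
direct effect (both mediators at their subject-specific counterfactual
values), there are *cross* contrasts that fix one mediator at a constant
level while letting the other take the natural value it would have had under
a reference exposure. With two mediators — possibly sequential, with $M_1$
affecting $M_2$ — five distinct cross contrasts exist:

| estimand name | contrast | model |
|---|---|---|
| `crossA_M1nat` | $\Delta E\{Y(x \to x', M_1(x_1), m_2)\}$ | either |
| `crossA_M2nat` | $\Delta E\{Y(x \to x', m_1, M_2(x_2))\}$ | either |
| `crossB_M2ctrl_inner` | $\Delta E\{Y(x \to x', m_1, M_2(x_2, m_1'))\}$ | sequential only |
| `crossB_M2nat_inner_nat` | $\Delta E\{Y(x \to x', m_1, M_2(x_2, M_1(x_3)))\}$ | sequential only |
| `crossB_bothnat_inner_ctrl` | $\Delta E\{Y(x \to x', M_1(x_1), M_2(x_2, m_1'))\}$ | sequential only |

Throughout, "dag A" denotes the variant in which the mediators do not affect
each other and "dag B" the variant with an $M_1 \to M_2$ arrow. Under dag A
the model is symmetric in the mediators, so `relabel_mediators()` maps each
estimand to its mirror image. One reading deserves note: under dag B the
contrast $\Delta E\{Y(x \to x', m_1, M_2(x_2))\}$ involves the *natural*
value of $M_2$ at exposure $x_2$, which there depends on $M_1$'s natural
value at $x_2$; the package therefore evaluates it as
$M_2(x_2, M_1(x_2))$ under dag B and as the parent-free $M_2(x_2)$ under
dag A. This keeps the estimand consistent with the structural equations of
each variant.

## Point identification: the g-formula

When all confounders of the mediator–outcome relationships are measured
(covariates $C$) and the exposure is randomized or unconfounded given $C$,
each component mean is identified by a standardization formula. For example,

$$E\{Y(x, M_1(x_1), m_2)\} = \frac{1}{n}\sum_{i=1}^n \sum_{m_1 \in \{0,1\}}
\hat P(Y{=}1 \mid C_i, x, m_1, m_2)\,
\hat P(M_1{=}m_1 \mid C_i, x_1),$$

and analogously with the $M_2$ model $\hat P(M_2 \mid C, X)$ (dag A) or
$\hat P(M_2 \mid C, X, M_1)$ (dag B), with a double sum for the contrasts
whose inner argument is itself natural. The covariate distribution is always
the empirical sample distribution. `fit_mediation_models()` fits the three
conditional models plus a marginal outcome model $\hat P(Y \mid C, X)$ used
only for the total effect; `po_mean_a()` through `po_mean_d()` evaluate the
four component-mean forms and `estimate_effect()` / `cross_effects()` take
contrasts.

Model forms:

* `"saturated"` (default without covariates): stratified empirical
  frequencies — the nonparametric MLE. On a dataset that enumerates a
  distribution exactly, these estimates reproduce the exact counterfactual
  means to numerical precision (the test suite checks 1e-10).
* `"main_effects"` / `"two_way"` (default with covariates): logistic
  regressions, the latter with all pairwise interactions among covariates,
  exposure and mediators.

Numerical policies: an empty saturated stratum yields `NaN` internally and
becomes an error (`crossmed_empty_stratum_error`) only if the estimand puts
positive weight on it; branches whose mediator-model weight is exactly zero
are skipped without evaluating the outcome model, so harmless empty cells
stay harmless. A logistic fit that fails to converge or separates falls back
to stratified frequencies with a `crossmed_nonconvergence_warning`. The total
effect uses raw arm means without covariates and standardizes
$\hat P(Y\mid C, X)$ over the covariate sample otherwise, because under dag A
the joint mediator law given $(C, X)$ is not part of the fitted model set.

## Partial identification: bounds under residual confounding

If unmeasured common causes $U$ of $\{M_1, M_2, Y\}$ remain, none of the
cross effects is identified and the package computes *tight* bounds — every
point of the reported interval is attainable by some causal model that
reproduces the observed data. The observed data enter only through the 16
conditional probabilities
$p_{y m_1 m_2 \cdot x} = P(Y{=}y, M_1{=}m_1, M_2{=}m_2 \mid X{=}x)$
(`observed_distribution()`); the bounds treat $X$ as randomized (marginally
or within a stratum of a categorical covariate — filter rows and rerun for
the latter).

Two routes are implemented and tested against each other:

**Closed form.** For the canonical contrasts (exposure 1 vs 0, all other
levels 0) the tight bounds are maxima/minima of small sets of linear
expressions in the 16 probabilities; `bounds_result1()` to
`bounds_result4()` and the dag-A swap `bounds_result1_swapped()` evaluate
them. The expressions are stored as coefficient *data*
(`bound_expression_table()`), not code, so each term can be inspected and
unit-tested, and the active expression indices are reported with each
interval. Intervals are never clipped to $[-1, 1]$: an interval escaping
that range signals an input that is not a valid per-arm distribution and
raises a warning instead of being masked. Closed forms for non-canonical
level settings are not transcribed; those requests are routed to the LP
engine with a message.

**Linear programming over response functions.** Because all four variables
are binary, the unmeasured confounder can be canonically partitioned into
finitely many *response functions*: each variable's structural equation is
one of the $2^{2^k}$ maps from its $k$ parents to $\{0,1\}$ — 4 for $M_1$,
4 (dag A) or 16 (dag B) for $M_2$, 256 for $Y$ — giving
$4 \times 4 \times 256 = 4096$ (dag A) or $4 \times 16 \times 256 = 16384$
(dag B) joint profiles. Any estimand's value is linear in the profile
distribution $q$, and the 16 observed probabilities constrain $q$ by a 0/1
incidence system $Aq = p$ (`build_lp()` keeps all 16 equalities literally;
they imply $\sum q = 1$). Minimizing and maximizing the objective over the
feasible set gives the tight bounds for *any* estimand at *any* level
setting (`solve_bounds()`).

The enumeration order is frozen so that $q$ vectors are portable: the
$M_1$-function index varies slowest, then $M_2$, then $Y$; within a
variable, functions are ordered by their truth table read as a binary
integer, inputs ordered lexicographically with $x$ slowest and the first
input as the most significant bit.

*How the LP is solved.* Every profile maps deterministically to one observed
cell per arm, so aggregating $q$ over the pair (cell under $x{=}0$, cell
under $x{=}1$) leaves an $8 \times 8$ transportation polytope whose row and
column sums are the two observed arm distributions. Within an aggregation
group the constraints cannot distinguish profiles, so for maximization all
of a group's mass may sit on a profile attaining the group's maximal
objective value (minimization: minimal); the reduced 64-variable
transportation LP therefore has exactly the same optimum as the full
4096/16384-variable program. The reduction is solved with the two-phase
simplex in the `boot` package after eliminating zero-mass rows and columns
(degenerate zero right-hand sides) and dropping the one redundant
constraint; the equality tolerance is $10^{-10}$ and intervals are only
rounded at presentation. The test suite cross-checks the reduced solve
against a direct full-size simplex solve of the 16-row program, against the
closed-form bounds on hundreds of Dirichlet-sampled compatible tables
(agreement to $10^{-6}$), and against enumeration ground truth (validity to
$10^{-8}$). Feasibility is guaranteed for any valid per-arm table because
the response-function model is saturated, so an infeasible solve is reported
as an `crossmed_lp_failure_error` rather than silently repaired.

The same machinery doubles as the synthetic-truth engine:
`sample_compatible_distribution()` draws $q$ from a symmetric Dirichlet and
marginalizes it; `true_effects_from_q()` evaluates any estimand exactly
under a known $q$.

## Inference

`bootstrap_ci()` implements the nonparametric percentile bootstrap:
records (rows, never aggregated cells) are resampled with replacement,
the statistic — which may be vector-valued, e.g. all five estimands from one
fit — is recomputed per replicate, and the interval is the pair of empirical
type-7 quantiles at $(1-\gamma)/2$ and $1-(1-\gamma)/2$. Defaults are
$B = 1000$ and level $0.95$; resampling is unstratified by default with a
`stratify_by_arm` option (the choice is documented rather than prescribed).
`bound_cis()` applies the same machinery separately to the lower and upper
bound endpoints. A replicate on which the statistic fails (an empty arm, an
empty stratum) is retried with a fresh resample up to a cap, then the run
errors. The full replicate matrix is kept on the result object so users can
post-process (e.g. BCa or boundary-adapted intervals, which the package does
not implement: the standard bootstrap is known to be inconsistent when the
true effect sits near the boundary of the bound interval, and no remedy is
attempted here).

## Synthetic data generators

`generate_covid_trial()` emulates a two-arm vaccine trial with continuous
immunological mediators: vaccination $X \sim \text{Bernoulli}(0.5)$; B-cell
response $M_1 \sim N(0.5 + 1.0X,\ \sigma^2 = 1)$ (note: *variance* 1);
antibody $M_2 = e^Z$, $Z \sim N(6.5 + 0.5X,\ \text{sd } 0.3)$; disease risk
$0.1$ under placebo and
$0.1\{\exp(-0.87 M_2 / 900) - 0.03 M_1 - 0.2\}$ under vaccination, clipped
to $[0,1]$; mediators dichotomized at $M_1 \ge 1$ and $M_2 \ge 1000$ for
analysis. One typeset reading of the vaccine-arm risk multiplies
$\exp(-0.87/900)$ by $M_2$ itself; since antibody is on the order of $e^7$,
that expression exceeds 1 a hundredfold and cannot be a probability, so the
package defaults to the antibody term inside the exponential and retains the
literal form only as `exponent_form = "literal"` for transparency. Under the
default, roughly 18% of vaccine-arm risks fall below zero and are clipped
(flagged by a `crossmed_dgp_clipping_warning` whenever the clip fraction
exceeds 10%, which it does at the defaults), and the implied overall vaccine
efficacy $1 - E[Y(1)]/E[Y(0)]$ computed by `scripts/acceptance.R` at
$n = 10^6$ comes out near 0.89 — close to, but slightly below, the 0.92 that
the mechanism is nominally calibrated to; without clipping the figure is
near 0.90. The gap is reported rather than hidden, and the acceptance test
for this quantity documents the same number.

A master seed is split into independent substreams for $X$, $M_1$, $M_2$ and
$Y$, so changing one component's parameters never shifts another component's
draws.

`generate_npsem()` simulates the binary structural model directly: one
response profile per subject drawn from $q$, a randomized exposure, and the
deterministic observation the profile generates. With `confounded = FALSE`
the profile law is an outer product of independent per-variable
response-function distributions — exactly the absence of residual
confounding — and the product structure holds to $10^{-12}$ by construction.
Exact ground truth for every estimand accompanies each dataset.

What these generators do *not* emulate: measured covariates (the COVID
mechanism has none, so covariate-adjusted estimation is exercised only on
generic logistic data in the tests), continuous-outcome mechanisms,
informative missingness, or realistic immunological correlation beyond the
designed mediator–outcome links. Tests passing on these generators therefore
establish the estimators' and bounds' *mathematical* behavior (consistency,
tightness, validity, coverage), not their adequacy for any particular real
trial.

## Study sizes used by the test suite

The package's own checks run at sizes chosen to finish comfortably on one
CPU: the efficacy check simulates one trial of $10^6$ subjects; the
tightness/validity properties use 200 Dirichlet-sampled compatible tables
per DAG variant (about 2,400 LP solves); the sampling-distribution study
uses 200 replications of $n = 5000$ with $B = 500$ bootstrap resamples,
under one fixed unconfounded product law and one fixed strongly confounded
mixture law. The confounded mixture couples $M_1$'s exposure response to
$Y$'s mediator response across two deterministic "worlds" (plus 10% uniform
smoothing so every observable cell stays populated); its saturated plug-in
limit is about 0.45 away from the true effect of the natural-$M_1$
estimands, which is what drives the bias and under-coverage demonstration.

## Known limitations

* Bounds require all four variables binary; continuous mediators must be
  dichotomized first (`dichotomize()`), and the information loss from
  dichotomization is not quantified by the package.
* Intermediate confounders (confounders of mediator–outcome affected by the
  exposure) are outside the model; no identification or bounds are offered
  for them.
* Closed-form bounds are available only at the canonical level settings;
  all other settings go through the LP engine.
* Percentile-bootstrap intervals for bound endpoints are not boundary-adapted.
* Covariates enter bounds only by stratified reruns, never inside the LP.
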