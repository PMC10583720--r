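# crossmed

Cross natural and controlled direct effects with two binary mediators.

## What problem this solves, and for whom

In trials and observational studies where a binary exposure $X$ acts on a
binary outcome $Y$ through two binary mediators $M_1$ and $M_2$ — for
example, vaccination acting on disease through a memory B-cell response and
circulating antibody — investigators often want the direct effect of the
exposure while *controlling one mediator to a fixed level* and *letting the
other take the natural value* it would have had under a reference exposure.
These "cross" contrasts sit between the classical controlled direct effect
(both mediators fixed) and natural direct effect (both natural). With two
possibly sequential mediators ($M_1 \to M_2$ allowed) there are five
distinct cross estimands, e.g.

$$\Delta E\{Y(1 \to 0, M_1(0), m_2)\} =
E\{Y(1, M_1(0), m_2)\} - E\{Y(0, M_1(0), m_2)\},$$

$$\Delta E\{Y(1 \to 0, m_1, M_2(x_2, m_1'))\}, \qquad
\Delta E\{Y(1 \to 0, M_1(x_1), M_2(x_2, m_1'))\}, \ \ldots$$

The package is aimed at biostatisticians and epidemiologists (vaccine
immunology is the motivating setting) and provides:

* **g-formula plug-in estimation** of every component mean
  $E\{Y(x, \cdot, \cdot)\}$ under no residual mediator–outcome confounding,
  with optional measured covariates (saturated frequencies or logistic
  models with two-way interactions);
* **tight nonparametric bounds** on the cross effects when residual
  confounding cannot be ruled out, by two mutually checking routes:
  closed-form expressions in the 16 observed probabilities
  $p_{y m_1 m_2 \cdot x} = P(Y{=}y, M_1{=}m_1, M_2{=}m_2 \mid X{=}x)$, and a
  linear program over the canonical response-function partition of the
  unmeasured confounder (4096 profiles when the mediators do not interact,
  16384 when $M_1 \to M_2$);
* **percentile-bootstrap confidence intervals** for point estimates and for
  bound endpoints;
* **synthetic-data generators** with exact ground truth, including a
  COVID-19-style vaccine-trial mechanism with continuous immunological
  mediators dichotomized for analysis.

See `vignettes/cross-direct-effects.Rmd` for the models, assumptions, and
numerical design choices.

## Worked example

Simulate a 1000-subject vaccine trial, dichotomize the mediators (B cells at
1, antibody at 1000 — done by the generator), estimate all cross effects
assuming no residual confounding, then compute bounds that allow for it:

```r
library(crossmed)
library(dplyr)

trial <- generate_covid_trial(1000, seed = 7)
#> Warning: 19.3% of vaccine-arm risks were clipped to [0, 1]
dat <- select(trial, x, m1, m2, y)

summarize_trial(dat)$arms
#>       x     n events
#> 1     0   483     48
#> 2     1   517      7

cross_effects(dat, dag = "B", model_form = "saturated")
#>                    estimand    estimate
#> 1              crossA_M1nat -0.07114539
#> 2              crossA_M2nat -0.07119977
#> 3       crossB_M2ctrl_inner -0.07118944
#> 4    crossB_M2nat_inner_nat -0.07119977
#> 5 crossB_bothnat_inner_ctrl -0.07212305
#> 6              total_effect -0.08583923

cross_bounds(dat, dag = "B", method = "symbolic")
#>                    estimand      lower     upper
#> 1              crossA_M1nat -0.1821946 0.9089027
#> 2              crossA_M2nat -0.3933747 0.9143210
#> 3       crossB_M2ctrl_inner -0.3933747 0.9296066
#> 4    crossB_M2nat_inner_nat -0.3933747 0.9143210
#> 5 crossB_bothnat_inner_ctrl -0.3933747 0.9296066
```

Every point estimate is negative — vaccination reduces disease risk through
each cross contrast — while the bounds, which drop the no-residual-
confounding assumption, still cover zero: the data alone cannot rule
confounding out. Bootstrap intervals for a bound's endpoints:

```r
sp <- effect_spec("crossA_M1nat", levels = list(x1 = 0, m2 = 0), dag = "B")
bound_cis(dat, sp, method = "symbolic", B = 500, seed = 7)
#> # A tibble: 2 × 4
#>   endpoint  point ci_lower ci_upper
#> 1 lower    -0.182   -0.217   -0.149
#> 2 upper     0.909    0.885    0.934
```

The same computations run from a shell via the thin CLI:

```sh
Rscript inst/cli/crossmed.R simulate --mechanism covid --n 1000 --seed 7 --sim-out trial.csv
Rscript inst/cli/crossmed.R effects --data trial.csv --dag B --model saturated --boot 500 --seed 7
Rscript inst/cli/crossmed.R bounds  --data trial.csv --dag B --method both
```

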