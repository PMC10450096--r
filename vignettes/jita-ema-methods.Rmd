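---
title: "Adaptive momentary assessment: models, design choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive momentary assessment: models, design choices, and what the simulations show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Just-in-time adaptive interventions deliver treatment at moments when a
person's state crosses a threshold — for example, when momentary fatigue is
elevated. The tailoring variable is usually measured with ecological
momentary assessment (EMA): brief self-report surveys delivered several
times per day. Two pressures collide here. Classification of a single
moment requires low measurement error, but every extra question raises
respondent burden across the dozens or hundreds of prompts of a study.

`jitaema` implements just-in-time adaptive EMA (JITA-EMA): at every prompt
a small computerized adaptive test (CAT) is run against a calibrated item
bank, with a stopping rule oriented toward *classification* rather than
uniform precision, and with classification cutoffs that can be tailored to
each person's diurnal rhythm. The package also ships a full synthetic-study
simulator and an evaluator so the design trade-offs can be quantified
before any real deployment.

## Psychometric model

Items follow the graded response model (GRM). For an item with
discrimination $a > 0$ and ordered thresholds $b_1 < \dots < b_{K-1}$, the
boundary curves are

$$P(X \ge k \mid \theta) = \mathrm{logit}^{-1}\!\big(a(\theta - b_k)\big),$$

and category probabilities are consecutive differences of these curves.
$\theta$ is the momentary latent state on a z-standardized metric (mean 0,
SD 1 in the norming population). Item Fisher information is
$I(\theta) = \sum_k P_k'(\theta)^2 / P_k(\theta)$.

Scoring is maximum a posteriori (MAP) under a normal prior, by default
$N(0, 1)$, for every condition and every prompt. The standard error of
measurement attached to an estimate is

$$\mathrm{SE}(\hat\theta) = \Big(\sigma_{prior}^{-2} +
\textstyle\sum_j I_j(\hat\theta)\Big)^{-1/2},$$

the standard CAT convention. Two numerical notes. First, the GRM
log-likelihood is concave, so the posterior mode is found by a damped
Newton iteration on the analytic score, clamped to $[-6, 6]$ (beyond six
prior SDs nothing is numerically distinguishable); tests pin the result to
a dense grid search within $10^{-3}$. Second, the SE formula is exactly
non-increasing in the number of items *at a fixed* $\theta$; because the
mode moves when a response is added, the re-evaluated information sum can
occasionally rise by $\sim 10^{-3}$. This has no practical effect on the
stopping rules and is asserted at that granularity in the tests.

Category probabilities in the far tails are computed on the complement
scale ($P(X \le k) = \mathrm{logit}^{-1}(-a(\theta - b_k))$) to avoid the
catastrophic cancellation a naive difference of near-one terms would
suffer.

## The adaptive session

Each EMA prompt runs one session (`start_session()` → `run_session()`):

* **Initialization.** The selection state starts at `init_theta` — the
  previous prompt's estimate (uniform-cutoff design) or the cosinor
  prediction for the current time of day (dynamic design). Initialization
  affects *only* which item is asked first; the scoring prior is untouched,
  so estimates remain comparable across conditions.
* **Item selection.** `random` (nonadaptive), `max_info` (information at
  the current selection theta), or `mei` — maximum expected information:
  for each candidate, the predictive category probabilities at the current
  MAP weight the candidate's information at the MAP recomputed as if that
  category had been answered. Predictive probabilities are evaluated at the
  point estimate, not integrated over the posterior: the simplest faithful
  reading of the criterion, and the one pinned by the brute-force oracle in
  the tests. Argmax ties break uniformly at random on the session's private
  seeded stream.
* **Stopping.** `fixed_length` (exactly $n$ items); `se_threshold` (SE
  below a bound — 0.3 by default, i.e. reliability $1 - 0.3^2 = 0.91$);
  or `classification_confidence`: stop as soon as the symmetric Wald
  interval $\hat\theta \pm z_{(1+c)/2}\,\mathrm{SE}$ excludes the cutoff
  ($c = 0.95$ by default). Every rule is capped at `max_items` (5).
* **Classification.** `above` iff $\hat\theta$ strictly exceeds the cutoff.
  When the interval straddles the cutoff at the item cap, the decision is
  forced at the point estimate — every prompt must yield a decision for
  sensitivity/specificity to be well defined. The Wald interval is
  symmetric; asymmetric error costs can be expressed through the
  `confidence` parameter of `classify()` but are not a default.

## Cutoffs

* **Uniform** (`cutoff_spec("uniform")`): one z value for everyone at all
  times; the default 1.0 is roughly the 85th percentile of the norming
  population.
* **Dynamic** (`cutoff_spec("dynamic")`): at each prompt a single-harmonic
  cosinor regression
  $\theta_i = \beta_0 + \beta_1 \sin(\tfrac{2\pi}{24}h_i) +
  \beta_2 \cos(\tfrac{2\pi}{24}h_i) + r_i$
  is refitted by OLS to all of the person's previously observed scores —
  including run-in and nighttime prompts, which exist precisely to feed
  this fit — and the cutoff is the prediction at the current hour plus
  `delta_sd` (default 0.5, a common minimally-important-difference
  benchmark) residual SDs. The residual SD uses denominator $n - 3$ (model
  degrees of freedom). With fewer than three observations or a
  rank-deficient design the cutoff falls back to
  $\bar\theta + \delta \cdot \mathrm{SD}(\theta)$. Cycles are treated as
  stationary within a study; no trend terms are fitted.

Classification under dynamic cutoffs is gated: the first `run_in_days`
(default 2) days and prompts outside the daytime window are never
classified. The window is half-open, $[6, 18)$ hours — a convention that
had to be fixed somewhere, chosen so that exactly twelve hours are
classifiable and tested at both boundaries.

## The synthetic study generator

The simulator emulates an intensive EMA study of momentary fatigue in a
chronic-pain population: 106 persons, 28 days, five to six prompts per day
stratified over a 6:00–22:00 waking window, each prompt completed with
probability 0.91 (missing completely at random). At full compliance this
yields roughly 16.3k momentary states per condition, matching the scale of
the observational data sets such designs are modeled on.

Each person carries a cosinor cycle plus noise:

* mean level $\beta_0 \sim N(0, 0.7)$;
* cycle amplitude $\sim U(0, 0.8)$ with uniform phase (split into
  $\beta_1, \beta_2$);
* within-person residual SD $\sim U(0.3, 0.9)$;
* day-to-day "wobble" SD $\sim U(0, 0.4)$, perturbing $(\beta_1, \beta_2)$
  each day — the inconsistency that makes person-specific cutoffs harder to
  estimate for some people than others.

These hyperpriors were chosen once so that the marginal variance of
generated states is approximately 1 ($0.7^2 + E[A^2]/2 + E[\sigma_w^2] +
E[\sigma_{day}^2] \approx 1.04$), because the latent metric is defined as
z-standardized; a Monte Carlo check in the tests requires the pooled SD to
fall in $[0.9, 1.1]$. True dynamic cutoffs use the person's *unperturbed*
cycle — the correct analogue of an estimated cutoff when the generating
truth is known. True classification is strict: a state exactly at the
cutoff is `below`.

What the generator does **not** emulate: informative missingness (only
MCAR compliance), item parameter drift or DIF, autocorrelated residuals
within days, and nonstationary cycles. Passing simulations therefore speak
to the *measurement* machinery under a plausible rhythm-plus-noise world,
not to robustness against those violations.

Five conditions run over shared truth — identical persons, schedules, true
states, true cutoffs, and response draws keyed by (prompt, item), so two
conditions administering the same item at the same prompt observe the same
answer; between-condition contrasts are then purely about item selection:

| condition | selection | stopping |
|---|---|---|
| `fixed2`/`fixed3`/`fixed5` | random | exactly 2/3/5 items |
| `variable` | random | 95% classification confidence, max 5 |
| `jita` | MEI, initialized from prior information | 95% classification confidence, max 5 |

During non-classifiable prompts of the dynamic design, the two adaptive
conditions fall back to the SE < 0.3 rule so that run-in scores are precise
enough to seed cutoff estimation.

## Evaluation

Sensitivity (specificity) is estimated among truly-above (truly-below)
classifiable prompts with a logit-normal random-intercept model — persons
as clusters — fitted by maximum likelihood with fixed 21-node Gauss–Hermite
quadrature; the inverse-logit of the intercept is the *median person's*
rate, which is what gets reported. This replaces the Bayesian multilevel
software fits such analyses often use with a fully self-contained estimator
of the same estimand; a test cross-checks it against `lme4::glmer` at
`nAGQ = 21` and against dense numerical integration. When all outcomes are
identical the model is degenerate; the estimate falls back to an
Agresti-style continuity-corrected pooled proportion and is flagged.

Cohen's kappa comes from the (sensitivity, specificity, prevalence)
identity with prevalence taken as the empirical truly-above rate among
classifiable prompts. Items-per-prompt variability is decomposed into
between- and within-person components by method-of-moments (one-way random
effects). Uncertainty for any summary is by seeded cluster bootstrap
(resampling persons); between-condition contrasts resample persons jointly
across conditions, preserving the shared-truth pairing.

Cutoff quality is tracked as the RMSE of observed minus true cutoffs by
study day (`cutoff_rmse_by_day()`): it declines over days as history
accumulates, is larger for persons with larger day-to-day wobble, and is
smaller for item-selection methods that measure each prompt more precisely.

## Problem sizes used by the test suite

The packaged checks replicate the two study designs at sizes chosen to
give stable orderings at desk scale: the ordering-replication test runs
20 seeds of a 28-person × 7-day study (a pilot showed the condition
orderings — kappa rising with fixed length, the adaptive condition beating
random selection on items at equal-or-better accuracy — hold with wide
margins there), while `scripts/acceptance.R` runs the full 106 × 28
reference design once per cutoff regime. Oracle checks (grid-search MAP,
brute-force MEI, quadrature vs dense integration) run at full fidelity.

## Known limitations

* One latent construct; no multivariate CAT, exposure control, or content
  balancing.
* MAP is the only scorer (no EAP/ML/weighted likelihood), and the Wald
  interval is the only stopping interval.
* The dynamic cutoff is a single-harmonic cosinor; sharper or multi-peaked
  rhythms would need more harmonics or splines.
* Reported sensitivities/specificities are median-person estimands; they
  are not pooled proportions, and with small clusters the two can differ
  noticeably.
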