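# jitaema

Just-in-time adaptive ecological momentary assessment (JITA-EMA) as a
reusable measurement toolkit.

## The problem

Just-in-time adaptive interventions (JITAI) trigger mobile treatment at
moments when a tailoring variable — say momentary fatigue — crosses a
threshold. The variable is measured with ecological momentary assessment
(EMA): short self-report surveys, several times a day, for weeks.
Measurement error in those surveys translates directly into false
positive and false negative intervention decisions, but longer surveys
burn out participants. JITA-EMA resolves the tension by running a tiny
computerized adaptive test (CAT) at every prompt: items are chosen
adaptively from a calibrated item bank and administration stops the moment
the person's current state is classified with requisite confidence.

The package is aimed at quantitative EMA/mHealth methodologists who want
to (a) run or prototype classification-oriented adaptive assessment
against a graded-response item bank, and (b) quantify, by simulation, what
different item-selection strategies buy in accuracy and burden before
fielding a study.

## What is inside

* **IRT core** — graded response model (GRM): category probabilities
  `P(X >= k | θ) = logit⁻¹(a(θ − b_k))` by differences, Fisher
  information, maximum a posteriori scoring under a `N(0, 1)` prior with
  `SE = (σ₀⁻² + Σ I_j(θ̂))^{-1/2}`, and response simulation.
* **CAT engine** — one session per EMA prompt: random / max-information /
  maximum-expected-information (MEI) item selection; fixed-length,
  SE-threshold, and classification-confidence stopping (stop when the
  Wald interval `θ̂ ± z·SE` excludes the cutoff; 5-item cap); strict
  above/below classification.
* **Cutoff engine** — uniform cutoffs (z = 1.0) or dynamic cutoffs:
  per-person cosinor regression
  `θ_i = β₀ + β₁ sin(2π/24 h_i) + β₂ cos(2π/24 h_i) + r_i` refitted at
  every prompt on all previously observed scores, cutoff = prediction at
  the current hour + 0.5 residual SDs, with a 2-day run-in and a 6:00–18:00
  daytime gate.
* **Study simulator** — synthetic populations with person-specific diurnal
  cycles, day-to-day cycle wobble and within-person noise, calibrated to a
  z metric; 28-day × 5–6-prompts/day schedules at 91% compliance; five
  item-selection conditions run over shared truth.
* **Evaluator** — per-person confusion counts; median-person sensitivity
  and specificity from a 21-node Gauss–Hermite random-intercept logistic
  model; Cohen's kappa from (Se, Sp, prevalence); items-per-prompt
  variance decomposition; weekly breakdowns; cutoff RMSE by day; cluster
  bootstrap comparisons.
* **CLI** — `make-bank`, `simulate`, `evaluate`, `session` subcommands
  (`inst/scripts/jita-ema`), YAML/JSON study configs, manifests with
  checksums.

## Worked example

Simulate a small uniform-cutoff study (10 persons, 7 days, all five
conditions over shared truth) and summarize it:

```r
library(jitaema)

study <- run_study(study_config(n_persons = 10, n_days = 7, master_seed = 3))
summarize_study(study)[, c("condition", "mean_items", "sensitivity",
                           "specificity", "kappa")]
```

```
  condition mean_items sensitivity specificity     kappa
1    fixed2   2.000000   0.5681875   0.9442379 0.5281980
2    fixed3   3.000000   0.6818160   0.9736194 0.6989698
3    fixed5   5.000000   0.7619347   0.9910268 0.8149653
4  variable   3.440729   0.7549646   0.9700901 0.7411300
5      jita   2.553191   0.8522832   0.9789476 0.8352405
```

Reading the table: each condition classified the same 329 prompts against
the uniform cutoff z = 1. The fixed-length rows show accuracy (kappa,
chance-corrected agreement between observed and true momentary
classifications) rising as more items are spent per prompt. The `variable`
row stops adaptively but picks items at random; `jita` adds MEI item
selection and prior-information initialization, and here classifies more
accurately than five fixed items while asking ~2.6 questions per prompt —
about half the burden. (At this toy size the estimates are noisy; the
acceptance script below runs the full-scale design.) Sensitivity/specificity are median-person rates
from the random-intercept logistic model, not pooled proportions.

A single adaptive session at one prompt, against your own item bank:

```r
bank <- generate_synthetic_bank(seed = 1)      # 13 items, 5 categories
s <- start_session(bank,
                   selector = selector_spec("mei"),
                   stopping = stopping_spec("classification_confidence"),
                   cutoff = 1.0, init_theta = 0.4)
run_session(s, function(item_id) 4L)           # a responder answering "4"
```

```
<prompt_result> 2 item(s) [item13, item05], stopped: confident
<theta_estimate> theta = 0.1636 (se = 0.3612), 2 item(s), map
<classification> below (confident), CI [-0.544, 0.872]
```

The same engine is scriptable from a shell:

```sh
Rscript inst/scripts/jita-ema make-bank --seed 1 --out bank.csv
Rscript inst/scripts/jita-ema simulate --config study.yaml --out runs/s1
Rscript inst/scripts/jita-ema evaluate --records runs/s1/records.csv --out runs/s1/eval --weekly
```

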