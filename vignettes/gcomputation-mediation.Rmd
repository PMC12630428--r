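---
title: "Counterfactual mediation by parametric g-computation: models, estimands, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual mediation by parametric g-computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Longitudinal birth-cohort studies ask whether an early-life exposure --
here, high childhood conduct problems -- affects an adult outcome --
hazardous alcohol use or current illicit drug use -- *through* a set of
adolescent experiences that may act as developmental "snares": police
arrest, gang membership, and school noncompletion. The causal structure
has four layers:

* **Baseline confounders** $C$ (sex, perinatal sociodemographic and
  health risk scores, maternal depression, family variables), measured
  before or contemporaneously with the exposure.
* **Exposure** $X \in \{0,1\}$, a dichotomized symptom score.
* **Intermediate confounders** $L$ (peer deviance, adolescent smoking
  and drinking, peer drug use, emotional problems): post-exposure
  variables that confound the mediator--outcome relationships and may
  themselves be affected by $X$.
* **Mediators** $M = (M_1, M_2, M_3)$ in temporal order (arrest by 18,
  gang membership 18--22, school noncompletion by 22), followed by the
  **outcome** $Y$ at 22.

Because the mediators' mutual causal ordering is uncertain, the package
estimates one *joint* indirect effect through the whole mediator block,
plus a single-mediator sensitivity analysis that promotes the earlier
snares to intermediate confounders.

# Estimands and the g-computation algorithm

For a scenario $(x_{\mathrm{dir}}, x_{\mathrm{med}})$ define the
counterfactual outcome prevalence $p(x_{\mathrm{dir}}, x_{\mathrm{med}})$
obtained when the direct pathway (intermediate confounders and the
outcome model) is driven by $x_{\mathrm{dir}}$ while the mediator block
is driven by $x_{\mathrm{med}}$. On the odds-ratio scale,

$$\mathrm{TCE} = \frac{\mathrm{odds}\,p(1,1)}{\mathrm{odds}\,p(0,0)},
\qquad
\mathrm{NDE} = \frac{\mathrm{odds}\,p(1,0)}{\mathrm{odds}\,p(0,0)},
\qquad
\mathrm{NIE} = \frac{\mathrm{odds}\,p(1,1)}{\mathrm{odds}\,p(1,0)},$$

so that $\mathrm{TCE} = \mathrm{NDE} \times \mathrm{NIE}$ holds *exactly*
whenever the three ratios are formed from the same three prevalences
(the package asserts this to $10^{-10}$). The proportion mediated is
$\ln(\mathrm{NIE})/\ln(\mathrm{TCE})$, reported as "n/a" under
inconsistent mediation (direct and indirect parts of opposite sign) or
when $|\ln \mathrm{TCE}| < 0.01$, where the ratio is numerically
meaningless. Numeric outcomes use mean differences, for which
$\mathrm{TCE} = \mathrm{NDE} + \mathrm{NIE}$ and
$\mathrm{PM} = \mathrm{NIE}/\mathrm{TCE}$.

`fit_model_system()` fits, on the listwise-complete rows, a logistic
model for each intermediate confounder given $(X, C,$ earlier $L)$, for
each mediator given $(X, C, L,$ earlier $M)$, and for the outcome given
$(X, C, L, M)$; all covariates enter linearly, as the field's staged
logistic analyses do. `estimate_effects()` then standardizes over the
empirical distribution of $C$: each complete-case row is replicated
`copies` times; $L^*$ is drawn sequentially under $x_{\mathrm{dir}}$, an
independent copy $\tilde L$ under $x_{\mathrm{med}}$, the mediator block
under $(x_{\mathrm{med}}, \tilde L)$, and the outcome model is evaluated
(not drawn -- this removes one layer of Monte Carlo noise) at
$(x_{\mathrm{dir}}, L^*, M)$.

## Interventional-analogue estimand

With exposure-induced mediator--outcome confounders, natural direct and
indirect effects are not nonparametrically identified. The package
therefore targets their *randomized interventional analogues*: the
mediator block is drawn from its counterfactual distribution under
$x_{\mathrm{med}}$ marginalized over an independent draw of the
intermediate confounders, while the outcome keeps its own draw $L^*$
under $x_{\mathrm{dir}}$. This is the standard resolution in the
g-formula mediation literature. All three scenarios -- including
$(1,1)$ and $(0,0)$ -- use the same construction, which is what makes
the odds-ratio decomposition exact. Users should read the reported
"natural" effects as interventional analogues whenever intermediate
confounders are present; how any particular published analysis resolved
this is usually not recoverable from its text, and the package makes its
own resolution explicit rather than implicit.

## Common random numbers

The scenarios reuse one seed-derived uniform stream (stored on the
logit scale, so each conditional draw is a single comparison). Under
common random numbers the scenarios share sub-draws -- $(1,0)$ reuses
the $L^*$ draw of $(1,1)$ and the mediator draw of $(0,0)$ -- so effect
*contrasts* carry far less simulation noise than the scenario means, and
a modest `copies` suffices. The default `copies = 100` replications of
the standardization rows keeps the residual Monte Carlo error on log
odds ratios an order of magnitude below typical sampling error at
$n \approx 4600$; the MC gap to exact enumeration is below $0.003$ in
absolute prevalence at `copies = 1000` and below $0.005$ at
`copies = 200`.

## Exact enumeration oracle

`exact_gformula()` computes the same estimand with *no* simulation
error, by summing over every configuration of the binary intermediate
confounders (under both exposure assignments) and the binary mediator
block, weighted by the model probabilities, and over the
baseline-confounder distribution -- the exact discrete support with
binomial weights for synthetic parameters, or the empirical
standardization rows for a fitted system. It exists so that every Monte
Carlo result in the package can be checked against an independent exact
number; it also supplies the ground-truth effects of the synthetic
generator (`true_mediation_effects()`). It refuses numeric variables:
the rounded, range-clipped numeric outcomes have no closed-form
standardized mean, so their ground truth falls back to large Monte
Carlo.

## Bootstrap confidence intervals

`bootstrap_effects()` implements the full-procedure nonparametric
bootstrap: every resample refits all component models and reruns the
counterfactual simulation, so the intervals reflect model-fitting
uncertainty, not just simulation noise. Standard errors are standard
deviations of the log odds ratios (or mean differences) across
resamples; intervals are normal-based around the full-sample point
estimate, exponentiated for ratios. `B = 50` mirrors the scale of
bootstrap used in the motivating literature; for production analyses we
recommend `B >= 200`. Resamples that fail (separation, a degenerate
counterfactual prevalence) are dropped and counted; more than 20%
failures raises a warning, or an error in strict mode.

# The synthetic cohort generator

No public individual-level data exist for the motivating study, so the
package ships a generator whose defaults *are* the study conditions: a
cohort of the same shape with known ground truth, so that every
downstream stage is testable end to end.

* Structure: six baseline confounders -- three binary (female sex 51%,
  parental separation 57%, parental smoking 73%), two bounded count
  scores entered linearly (sociodemographic/health risk 0--5, mean 0.90;
  maternal depression 0--20, mean 5.69), and the comorbidity confounder
  hyperactivity (0--10, mean 4.3) -- a binary exposure, five binary
  intermediate confounders (peer deviance, adolescent smoking and
  drinking, peer drug use, high emotional problems), the three binary
  mediators in temporal order, two binary outcomes, and two numeric
  alcohol subscale outcomes (consumption 0--12, problems 0--28)
  generated as rounded, range-clipped linear responses -- a deliberate,
  documented deviation from pure linearity.
* Calibration: slope coefficients are fixed plausible log odds encoding
  every arrow of the causal diagram (all exposure-to-mediator and
  mediator-to-outcome arrows nonzero, so mediation exists by
  construction); intercepts were solved sequentially by large-sample
  simulation ($n = 2 \times 10^6$) so the six key marginal prevalences
  match the study's descriptive table: exposure 31%, arrest 3.8%, gang
  membership 2.2%, school noncompletion 43%, hazardous alcohol 22%,
  illicit drug use 14% (arrest and gang calibrated inside the printed
  confidence bands rather than at the rounded integers).
* What it does *not* emulate: joint mediator overlap beyond what the
  sequential logistic structure implies (the study does not report joint
  prevalences, so e.g. the arrest-and-gang overlap is a free
  consequence of the arrest coefficient inside the gang equation);
  measurement error; repeated measures; any non-logistic link. Passing
  recovery tests therefore show that the estimator works when its
  parametric models are correctly specified -- they cannot certify
  robustness to real-data misspecification.
* Missingness: `impose_missingness()` masks only post-exposure columns
  (a birth cohort's perinatal data are complete), with a per-cell
  logistic probability driven by the exposure and baseline confounders
  -- never by the masked value -- and an intercept solved so the overall
  masked fraction equals the configured rate (default 0.06 per cell,
  which leaves roughly half of rows fully complete, the completeness
  ratio the motivating study reports). Exposed children are more often
  incomplete, mimicking selective attrition.
* Seed policy: one root seed; every variable, masking column, bootstrap
  replicate, and imputation draws from a deterministically derived
  substream, so identical inputs give bitwise-identical outputs.

# Missing data

`impute_chained()` is multivariate imputation by chained equations:
random-fill initialization, then cyclic sweeps (default 10) over
incomplete columns in increasing missingness order; binary columns are
redrawn from a logistic conditional, numeric columns from a linear
conditional with residual noise, and each conditional's coefficients are
perturbed by a draw from their approximate posterior so between-imputation
variance is properly propagated. Every other column participates as a
predictor -- including auxiliary columns outside the analysis roles,
mirroring the "strong auxiliary variables" strategy -- which keeps the
imputation models congenial with the analysis models (all main effects,
no interactions). `m = 40` mirrors the motivating analysis.
`pool_rubin()` applies Rubin's rules (total variance = within +
$(1 + 1/m)\times$ between) with normal-based intervals by default and
the Barnard--Rubin small-sample correction behind a flag, matching the
normal-based style of the reported intervals. `pooled_mediation()` runs
the bootstrap within each completed data set and pools each effect on
its log scale with the bootstrap variance as the within-imputation
variance.

# The study pipeline

`run_study()` executes the full analysis in the staged structure of the
motivating study: descriptive table (percent or mean with Wald
intervals; Wilson behind a flag); exposure-mediator associations in
three stages (unadjusted; baseline confounders; additionally the
baseline comorbidity confounder -- deliberately *without* intermediate
confounders, which is how the corresponding figure in the motivating
analysis is captioned); mediator-outcome associations in four stages
(unadjusted; exposure + baseline + intermediate confounders;
additionally comorbidity; additionally all mediators); the three-mediator
g-formula per outcome in three adjustment tiers; and the sensitivity
analyses (single-mediator model for the last mediator, complete-case
versus imputed comparison, numeric subscale outcomes). When the cohort
has missing cells, association tables and mediation effects are
Rubin-pooled over chained-equation imputations. Every stochastic stage
derives its seed from the configuration seed, so regenerating a report
is byte-identical.

# Numerical choices

* Logistic fitting is iteratively reweighted least squares via
  `stats::glm.fit` on a numeric design matrix, deviance tolerance
  $10^{-10}$, 100 iterations; Wald covariance from the observed
  information.
* Separation -- a real concern with a 2% mediator inside bootstrap
  resamples -- is detected as non-convergence or any non-intercept
  coefficient beyond $\pm 15$, and resolved by a ridge-penalized refit
  ($\lambda = 10^{-4}$ on non-intercept terms) carrying an annotation;
  component separation inside a model system is reported in the system
  and in effect metadata, never silently.
* A counterfactual prevalence of exactly 0 or 1 raises an
  "undefined odds" error naming the scenario rather than returning an
  infinite ratio.
* The proportion-mediated "n/a" threshold $|\ln \mathrm{TCE}| < 0.01$
  is an implementation choice: below it the log-ratio is dominated by
  rounding of its inputs.
* Degenerate inputs: intercept-only models, empty intermediate-confounder
  blocks, and empty adjustment sets are all valid (the unadjusted tier
  is exactly such a system).

# Problem sizes used in the shipped experiments

The test-suite experiments run at the study's own scale where that is
what is being claimed (cohorts of $n = 4599$, $B = 50$ bootstrap
resamples, 40--50 simulation replicates for recovery and coverage), and
at reduced Monte Carlo sizes where only a contrast of methods is being
demonstrated (e.g. `copies = 15` inside bootstrap resamples, `m = 5`
imputations in the attrition experiment, masking rate 0.12 in the
complete-case comparison so that listwise deletion visibly loses
efficiency). The calibration check generates $10^6$ rows. These sizes
are the package's own choices of experimental design, set by the
variance of the quantity each experiment measures.

# Known limitations

* Natural effects are reported as interventional analogues (above);
  with no intermediate confounders they coincide with classical natural
  effects.
* The joint-block NIE depends on the declared mediator order only
  through the sequential block factorization; the order is reported in
  effect metadata and configurable.
* No time-varying exposures, inverse-probability weighting, doubly
  robust estimation, or exposure-mediator interaction decompositions.
* Imputation offers no predictive-mean matching or multilevel models;
  all analysis variables here are binary or numeric scores.
* The synthetic generator matches marginals and the qualitative causal
  graph, not the joint distribution of any real cohort.
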