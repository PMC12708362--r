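---
title: "Scoring and effect estimation for a pesticide-safety cluster trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and effect estimation for a pesticide-safety cluster trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kapeis)
```

## The study design this package models

`kapeis` implements the outcome-construction and effect-estimation
computations of a three-arm cluster-randomized pesticide-safety trial
among smallholder farmers: twelve subcounties (clusters) randomized
1:1:1 to a control arm, a two-day educational intervention, or the
education plus a text-message program, with structured interviews at
baseline and at a 12-month follow-up. Three families of outcomes are
derived from the questionnaire: knowledge/attitude/practice (KAP)
scores, a semi-quantitative Exposure Intensity Score (EIS) for
pesticide application, and a count of self-reported poisoning signs and
symptoms. Because the field data are not public, a synthetic cohort
generator reproduces the trial's statistical structure so that every
stage of the pipeline is testable end to end.

## Outcome construction

**KAP scores.** Each domain has 15 items. Knowledge items are
categorical (1 = yes, 2 = no, 3 = do not know) and keyed per item
(default key "yes"); a matching response scores 1, anything else —
including "do not know" — scores 0. Attitude and practice items are
5-point Likert responses; negatively worded items are reverse-scored
(`r` becomes `6 - r`) before dichotomizing 1–3 to 0 and 4–5 to 1;
"no opinion" codes to missing. Domain scores are the 0–15 item sums.
The default missing-item policy is *complete-domain*: any missing item
makes the domain score missing, matching a complete-case analysis. An
*available-item prorating* policy (`missing_policy = "prorate"`) is
selectable but never the default. Scores are kept exact internally;
percents of maximum (score/15, EIS/13, count/31, sub-scores/1) are
rounded to one decimal only at the reporting layer
(`report_percent()`).

**Exposure Intensity Score.** Two tasks raise exposure — mixing
pesticides (weight 5) and applying with a knapsack sprayer (weight 8) —
and three factors scale it down: the PPE sub-score over six body parts
(range 0.1–1; *higher means more exposed*), and the time-to-change and
time-to-shower hygiene factors (each 0.7–1). The published formula,

$$EIS = MIX + APPLICATION \times PPE \times CHANGE \times SHOWER,$$

is printed without parentheses. Under standard operator precedence the
protective factors modify the application weight only; that reading is
the default (`eis_variant = "literal"`). The parenthesized reading
$(MIX + APPLICATION) \times PPE \times CHANGE \times SHOWER$, in the
spirit of the predecessor exposure algorithms, is available as
`"modified_sum"`. Which reading the original analysis used cannot be
determined from the published text, so both are implemented and
regression-tested and neither is asserted as "the" published one; they
agree at the no-protection corner and both span 0–13 exactly.

The published algorithm fixes only the six-part sum and the 0.1–1
range; per-part weights and the access-by-frequency mapping are not
printed. The default codebook uses equal weights ($w_p = 1/6$, minimum
contribution $m_p = 0.1/6$) and the frequency map never 0, rarely 0.25,
sometimes 0.5, often 0.75, always 1, with lack of access forcing 0.
Each part contributes $w_p - f_p\,(w_p - m_p)$ for protection fraction
$f_p$. Hygiene categories are likewise unpublished beyond their range;
the default three-level map is immediate 0.7, same-day 0.85 (the range
midpoint), later 1.0. All of these sit in a human-editable YAML
codebook, not in code, because the instrument publishes item counts
but not item texts; shipped labels are placeholders. Participants who
neither mix nor apply score 0 and are retained — a degenerate-input
guard, since eligibility required recent application.

**Symptoms.** A plain count of 31 binary indicators, reported also as
percent of 31.

## Effect estimation

For each outcome $Y$ on the percent-of-maximum scale, the estimator is
the baseline-adjusted mixed-effects ANCOVA

$$Y^{fu}_{ij} = \alpha + \beta_1\,\mathrm{edu}_{j} +
\beta_2\,\mathrm{eduSMS}_{j} + \gamma\,Y^{base}_{ij} + b_j +
\varepsilon_{ij}, \qquad b_j \sim N(0, \sigma^2_c),$$

with a random intercept per cluster, fitted by REML, control as the
reference arm, and arm coefficients read as percent-point differences.
Rows enter a model only when the outcome is observed at both waves and
(for the adjusted variant) all covariates are present — complete-case,
intention-to-treat by assigned arm. Two sensitivity variants mirror the
trial's: `"adjusted"` adds age group (below/above 40), sex, education,
income and prior training (constant covariates are dropped, so a
degenerate design reduces exactly to the primary model), and
`"combined"` pools both intervention arms into one indicator.
Sub-component models refit the same form with the PPE, change and
shower sub-scores as outcomes.

**Inference with twelve clusters.** Arm contrasts in a cluster trial
are between-cluster comparisons; with 12 clusters their effective
denominator degrees of freedom are roughly 8–9, and large-sample z
intervals are visibly anticonservative (about 8% type-I error where 5%
is nominal, since $2\,P(t_9 > 1.96) \approx 0.08$). The default is
therefore Satterthwaite t inference on the fixed effects
(`ci_method = "satterthwaite"`, via lmerTest), the standard choice for
few-cluster designs; large-sample z intervals remain available as
`ci_method = "wald"`. Significance is two-sided at 0.05. Small-sample
corrections beyond Satterthwaite (e.g. Kenward–Roger) are out of
scope. If the cluster variance is estimated at zero, the fit is
singular and the function falls back to the fixed-effects
least-squares model with a warning rather than failing; in that case
its estimates coincide with the closed-form ANCOVA solution, which the
tests verify against an independent normal-equations oracle.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated. For each outcome, latent percent-scale values follow

$$y_{ijw} = \mu + \Delta_{a(j)}\,[w = fu] + b_j + e_{ijw},$$

with $b_j \sim N(0, \sigma^2\,\rho_{ICC})$ shared across waves,
residuals $e$ with variance $\sigma^2 (1 - \rho_{ICC})$ and
between-wave residual correlation $\rho_{bf}$ (so total wave-to-wave
correlation is $\rho_{ICC} + (1-\rho_{ICC})\rho_{bf}$). Defaults are
the trial's structure: 12 clusters, arms of 180/180/179, ICC 0.4 (the
trial's sample-size assumption), 13% loss to follow-up
(missing-completely-at-random by default; an optional mode ties
dropout odds to baseline practice for robustness experiments), and
baseline means/SDs and follow-up arm effects equal to the reported
values (`default_outcomes()`). Two values are free parameters the
trial does not report and were fixed once as realistic:
$\rho_{bf} = 0.5$, and a symptom-score SD of 10 percent points (the
same order as the other outcomes' 11–16).

Latent values are clamped to [0, 100] and inverse-mapped to raw
responses: KAP domains draw 15 Bernoulli(latent/100) correctness
indicators and emit responses that code back to them through the
codebook (keys and reverse flags respected); symptoms draw 31
indicators; for the EIS the generator enumerates the achievable
lattice of (mix, application, PPE quarter-steps, hygiene categories),
and picks the deterministic nearest EIS to the target. Effects are
injected on the latent percent scale — the scale on which coefficients
are reported — rather than per item, the simplest structure consistent
with the analysis model.

**What the generator does and does not emulate.** It reproduces the
cluster correlation, wave correlation, arm effects, attrition and the
discreteness of all outcomes. It does not emulate item-level
difficulty structure, correlations *between* outcomes (reported only
as weak), informative attrition (except the optional mode), or
interviewer/translation effects. Passing recovery tests therefore
demonstrates that the estimator recovers effects under the trial's
design parameters, not that any field dataset would behave this way.
Two approximations matter near the scale boundaries: the latent normal
is clamped, which compresses means toward the interior by a few tenths
of a percent point for outcomes near a boundary (attitude at ~79%,
symptoms at ~16%) — validation tests compare against the closed-form
clamped-normal mean, and simulation recovery stays within the ±0.5
percent-point band used in the calibration suite; and the EIS input
lattice is coarse, so per-participant EIS targets are hit only to the
nearest achievable value.

## Design machinery

`design_effect(m, icc)` is the standard inflation $1 + (m-1)\rho$.
`sample_size_two_means()` uses the normal-approximation two-sample
formula and then applies the design effect *self-consistently*
($m = n/k$ must itself satisfy the inflated equation), giving
$n = n_0(1-\rho)/(1 - n_0\rho/k)$, which has no positive solution when
$k \le n_0\rho$. With the published inputs (EIS means 0.47 vs 0.55,
SDs 0.10 and 0.18, 80% power) the unadjusted per-arm n is 52; at ICC
0.4 with 4 clusters per arm the design is infeasible under this
formula, and the module reports that diagnosis rather than
reverse-engineering the trial's published total of 540 — transparency
over false agreement. (The published effect-size inputs are on a 0–1
style EIS scale from an earlier survey, not the 0–13 scale used here;
they are treated as given.) A t-based refinement of the z formula is
out of scope. `consort_flow()` recomputes every percentage from
integer counts at render time.

## Numerical and reproducibility choices

Every stochastic entry point (`generate_cohort()`,
`randomize_clusters()`, `run_pipeline()` in simulation mode) requires
an explicit seed and is byte-reproducible given one. Nearest-EIS ties
break deterministically to the lower value; lattice representatives
are chosen by a fixed sort order. CSV I/O uses UTF-8, comma
separators, and the literal token `NA` for missing; Likert responses
are stored as tokens "1".."5" plus `no_opinion` so that a non-numeric
response can never be silently coerced to a number. Validation errors
name the row and field.

## Problem sizes used in the test suite

The calibration suites run at the trial's size (539 participants, 12
clusters): 500 replicate cohorts for effect recovery (mean estimate
within ±0.5 percent points of the generating effect) and 1,000
replicates for type-I calibration (non-coverage of zero within
[3%, 7%]). Structural and property tests use smaller cohorts
(40–250 per arm); the generator-ICC check averages the ANOVA ICC
estimator over 20 cohorts of 1,200 because a single 12-cluster cohort
estimates the ICC with sampling SD near 0.1, which would test the
draw rather than the generator.

## Known limitations

* No multiple imputation (the motivating analysis fell back to
  complete cases after non-convergence) and no modelling of
  between-outcome correlation or mediation (e.g. PPE change to symptom
  change).
* EIS is not adjusted for annual application days.
* The per-part PPE weights, frequency map and hygiene maps are
  field-standard defaults, not published values; conclusions about
  sub-components inherit that choice (they are codebook-overridable).
* Wald/Satterthwaite intervals are the only options; no bootstrap or
  permutation inference.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config()
coh <- generate_cohort(cfg, seed = 1)
scores <- score_records(coh$records)
fit_primary(scores, "knowledge_pct")
run_pipeline(tempfile("run"), seed = 1, config = cfg)
```
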