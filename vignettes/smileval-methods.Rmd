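---
title: "Models and methods in smileval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in smileval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smileval)
```

`smileval` implements a pipeline linking the laboratory-measured subjective
value of genuine smiles to smile reciprocity in naturalistic dyadic
interaction: a logistic choice-utility model, value-driven attentional
capture scoring, facial action unit (AU) based reciprocity detection, and an
actor–partner interdependence model (APIM). Because the behavioural data the
pipeline was designed for are not redistributable, the package ships a
synthetic-data generator with known ground truth; every stage is validated
by parameter recovery against that truth.

## The choice-utility model

In the valuation task, six face "players" cross social display (genuine
smile, polite smile, neutral-with-text) with monetary value: each display
type appears once as a high-value player (2¢ won on 80% of trials, expected
value 1.6¢/trial) and once as a low-value player (2¢ on 60%, 1.2¢/trial).
After 30 exposures per face, the test phase shows all 15 pairings 8 times
each (120 trials), with each face on the left for half of its pair's trials.

The probability of choosing the left face is modelled as

$$P(\text{left}) = \frac{e^\theta}{1+e^\theta},\qquad
\theta = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_3,$$

where $X_1 \in \{-.40, 0, .40\}$ codes the expected-value difference
(positive when the left face is the high-value player), and $X_2, X_3 \in
\{-1, 0, 1\}$ code genuine and polite smiles (e.g. $X_2 = 1$ when only the
left face smiled genuinely, $0$ when both or neither did). The fitted
weights $\beta_1,\beta_2,\beta_3$ are the participant's utilities of money,
genuine smiles and polite smiles on the logit scale.

`fit_utilities()` maximizes the Bernoulli likelihood per participant by
iteratively re-weighted least squares (IRLS, i.e. Newton scoring with
step-halving). Two numerical safeguards matter for per-participant fits with
120 trials, which can separate:

* a ridge penalty $\lambda \|\beta\|^2$ with $\lambda = 10^{-4}$ keeps the
  optimum finite under complete or quasi-complete separation without
  measurably biasing well-behaved fits (the penalty's gradient is four
  orders of magnitude below the data's);
* estimates are capped at $|\beta| \le 10$; a fit at the cap (or one that
  exhausts its iterations) is flagged `converged = FALSE`.

A regressor that never varies over a participant's trials (possible only
with non-standard designs) carries no information and its weight is
reported `NA`. The test suite cross-checks IRLS against `glm()` and against
a derivative-free coordinate grid-search maximizer of the same penalized
likelihood; agreement is required to $10^{-2}$.

Group-level inference uses Wilcoxon signed-rank tests (the utility
distributions are heavy-tailed), with the matched-pairs rank-biserial
correlation $r = 2V/S - 1$ as effect size ($V$ the positive-rank sum, $S$
the total rank sum). The exact signed-rank null distribution is used for
$n \le 25$ tie-free differences, a normal approximation with continuity and
tie corrections otherwise; zero differences are dropped (Wilcoxon
convention). The rank-biserial CI is a 2000-resample bootstrap percentile
interval; no analytic interval is standard for this statistic.

Split-half reliability (`split_half_reliability()`) refits the model on
odd- and even-indexed trial halves — a split that preserves pair-type
balance — and correlates half-estimates across participants. No
Spearman–Brown step-up is applied by default; it is available by argument.

## Attentional capture scoring

Error trials are discarded; each participant's grand-average search RT is
computed over all retained trials — including the all-novel-distractor
trials, since the grand mean is a device for removing between-participant
nuisance (hardware, baseline speed), not a design cell — and subtracted
from each condition's mean RT. The exact centering identity (trial-weighted
deviations sum to zero) is asserted in tests. The genuine-capture composite
is the mean of the two genuine-distractor centered means minus the mean of
the two neutral ones; positive values mean genuine-associated faces slowed
search more.

`rm_anova_2x3()` analyses the six familiar-distractor cells as a fully
within-participants 2 (money) × 3 (social) ANOVA, each effect tested
against its own effect-by-participant stratum; the all-novel condition is
not part of the factorial design and is reported descriptively only. No
sphericity correction is applied by default, matching the use of
uncorrected degrees of freedom in this design's standard reporting. Effect
sizes are partial omega-squared computed from $F$:
$\hat\omega^2_p = \frac{df_1 (F-1)}{df_1 (F-1) + n}$ with $n$ the number of
participants; variants based on raw sums of squares differ slightly, and
the F-based form was chosen because it is well-defined for any balanced
within-subject stratum. Post-hoc paired $t$ contrasts (social levels
pairwise; money within each social level) are Bonferroni-corrected within
family.

## Reciprocity detection

AU series arrive at 15 frames/s (one frame spans $1000/15 = 66.7$ ms), on a
shared frame clock per dyad. A frame is a genuine (Duchenne) smile when
both the lip-corner puller AU12 and the cheek raiser AU06 exceed the
activation threshold $\tau$, a polite smile when AU12 alone does. $\tau$
defaults to 0 (any positive activation) and is a parameter rather than a
constant because automated AU coders apply internal calibrations that are
not observable downstream.

Maximal runs of smiling frames become events; a run containing any genuine
frame is one genuine event. The alternative — splitting a run at every
type change — is available (`split_on_type_change`), but the default treats
a polite-to-genuine transition as one evolving smile, which avoids
manufacturing same-frame "reciprocity" out of a single facial action. A
minimum-duration filter (off by default) is exposed for noisy AU streams.

Matching scans every event of both members as a potential initiation. An
initiation is reciprocated if the partner produces a same-type onset in the
window $(t, t + 60]$ frames (4 s inclusive at the far end). Same-frame
onsets never count — a responder cannot react in zero frames; near-
synchronous smiles are a real phenomenon, but crediting them as
reciprocation would make the initiator label arbitrary. Each responder
event answers at most one initiation; the earliest unmatched initiation
wins and takes the earliest available responder event. Initiations too
close to the session end to be answerable are kept in denominators by
default (the naïve script behaviour); a flag excludes them. Lags are
reported in frames and in ms (×1000/15).

## The APIM

For indistinguishable (exchangeable) dyad members with predictor $x$
(genuine reciprocity speed) and outcome $y$ (interaction-quality rating):

$$y_1 = a_0 + a x_1 + p x_2 + e_1,\qquad y_2 = a_0 + a x_2 + p x_1 + e_2,$$

with actor path $a$, partner path $p$, predictor means/variances and
residual variances constrained equal across members, and within-dyad
covariances of predictors and residuals free. Estimation is direct maximum
likelihood on the dyad-level 4-variate Gaussian $(x_1,x_2,y_1,y_2)$, not a
wrapper around an external SEM engine, which keeps the module
self-contained and testable against oracles:

* **Complete data.** The equality constraints are exactly invariance under
  swapping the members; the constrained MLE is therefore the swap-average
  of the saturated moment estimates, from which the eight model parameters
  are recovered in closed form. This is exact, deterministic and fast
  enough to bootstrap heavily.
* **Missing outcomes.** The casewise (full-information) log-likelihood over
  each dyad's observed entries is maximized numerically (BFGS over an
  unconstrained parameterization: log-variances, atanh-correlations),
  started from the complete-case closed form. The two routes agree on
  complete data, which the test suite asserts.

The model has 8 parameters against the 14 of the saturated 4-variate
Gaussian, so the likelihood-ratio model test has 6 degrees of freedom. The
saturated (distinguishable) model is used as the comparison because the
equality constraints *are* the substantive restriction being tested; an
exchangeable-saturated baseline would leave zero degrees of freedom for
this model, since the APIM with free residual covariance reparameterizes it
exactly. RMSEA, CFI and TLI are computed from that chi-square with an
independence baseline; SRMR uses standardized covariance residuals on
complete cases.

Paths are standardized with model-implied variances. Inference on the
standardized paths is by bias-corrected (BC, not BCa) bootstrap, resampling
dyads, 1000 resamples by default; reported SEs and $z$/$p$ values are
bootstrap-based, so with `n_boot = 0` only point estimates and fit indices
are returned. Alternate-predictor models (proportion of genuine smiles
reciprocated; polite reciprocity speed) reuse the same fitting contract.

Interaction quality is the mean of 9 Likert items (1–7) after reverse-
scoring ($8 - x$); internal consistency is Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i \sigma_i^2 / \sigma_T^2\bigr)$ with
a Feldt F-based confidence interval.

## The synthetic-data generator

The generator reproduces the task designs exactly (180 exposure trials, 120
test trials with left/right balance, 252 search trials with 36 per
familiar-distractor condition and quadrant-balanced targets) and draws:

* utility weights from the population spread observed for this family of
  tasks — money mean .665 (SD 1.095), genuine mean 1.042 (SD 1.565); the
  polite mean (0.3, SD 1.0) and intercept (0, SD 0.3) are not reported
  anywhere and were fixed once at plausible values;
* search RTs as baseline + condition shift + lognormal noise (right-skewed
  and positive, the canonical RT noise family). Default shifts were
  back-calculated from the effect sizes reported for this paradigm
  (genuine−neutral composite 0.125 s, polite−neutral 0.089 s, a 0.060 s
  money effect confined to neutral faces);
* smile episodes from Poisson processes at 1.2 genuine and 0.8 polite
  events/min — interaction studies of strangers typically report one to
  three smiles per minute, and no base rates are printed for this
  paradigm — with durations uniform on 8–45 frames and same-member
  overlaps merged (genuine dominating);
* reciprocation with probability .72 (genuine) / .57 (polite) at lags from
  a truncated normal on [1, 60] frames with member-level means centred on
  14 (genuine) and 21 (polite) frames, the values implied by the reported
  939 ms and 1413 ms group means. Lag 0 is never generated, so "initiator"
  is always well defined in truth logs;
* ratings from latent actor/partner effects of genuine reciprocity speed,
  expressed through nine unit-loading items with noise, thresholded to the
  7-point scale, two items stored reverse-keyed.

Reproducibility: all randomness flows from one seed; each participant,
dyad, and bootstrap derives a deterministic child seed, so any subset of
units regenerates identically on its own.

Two generator properties deserve honesty about what recovery tests show.
First, the event-level matching rules are one-to-one and chronological, so
in dense smile traffic a responder event can be "taken" by a neighbouring
initiation; measured per-member proportions are therefore biased relative
to the generating probability when rates are high. Recovery is assessed by
joining pipeline matches back to the truth log of spontaneous initiations
(`reciprocity_recovery()`), which is the well-defined round trip. Second,
Likert discretization censors the latent rating at the scale ends; the
recovery generator (`simulate_apim_dyads()`) centres the latent scale at
the midpoint so standardized paths are not attenuated by ceiling effects.
The cohort generator keeps a realistic high-end intercept (5 of 7) for
descriptive realism instead.

What the generator does **not** emulate: real AU estimation noise
(activations are clean 0/0.9 step functions), head motion and occlusion
artefacts, non-stationary smile rates over a conversation, and any
dependence of RT noise on condition. Passing recovery tests therefore shows
the estimators are correct for their models, not that the models capture
every property of real video data.

## Problem sizes and tolerances in the test suite

The validation suite uses sizes chosen to keep Monte-Carlo error well below
the asserted tolerances: 200 participants × 120 trials for utility recovery
(true-vs-estimated correlation > .8); 200 dyads for reciprocity round trips
(proportions within ±.03, lags within ±2 frames); 500 dyads, 200 bootstrap
resamples and 200 replicates for APIM recovery and CI coverage (partner
path within ±.05, coverage 95% ± 6 points, the binomial error of 200
replicates plus residual discretization bias); 1000 replicates for the
ANOVA type-I error (nominal .05, asserted within [.03, .07]).

## Known limitations

* The AU threshold $\tau$, the same-frame tie rule, and the end-of-session
  denominator rule are parameters because the upstream conventions they
  mirror are not observable; conclusions sensitive to them should be
  checked across settings.
* The APIM here is the indistinguishable-dyad, single-predictor variant
  only: no distinguishable roles, no multilevel extension, no mediation.
* `fit_alternate_models()` refits marginal models per predictor; it does
  not adjudicate between correlated predictors jointly.
* With `n_boot = 0` the APIM reports no SEs; the bootstrap is the only
  inference path implemented, matching how such models are usually
  reported.
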