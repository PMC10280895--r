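---
title: "Scoring micro-coded facial expressions during Cyberball: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring micro-coded facial expressions during Cyberball}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyberscore)
```

## The measurement problem

Cyberball is a computerized ball-tossing paradigm that induces social
exclusion: after a short Inclusion Period (six tosses, the participant
receives tosses 3 and 6) the two avatars stop throwing to the
participant for 36 further tosses, except tosses 15 and 25 which retain
attention.  Children's facial expressions of sadness, anger and
contempt are coded continuously (0–5 intensity per channel, with a
visibility flag) by human coders watching the webcam video.  The
package turns such traces into per-child scores and runs the
epidemiological association analyses around them; because the cohorts
this design targets are access-restricted, a calibrated synthetic
generator stands in for real data and doubles as the test bed for
every pipeline stage.

## From trace to score

**AUC.**  For a channel and a period window, the score is the
trapezoid integral of the intensity curve over the *visible*
sub-intervals of the window, divided by the visible seconds and
multiplied by 10 — an average AUC per 10 s of visible time, in
$[0, 50]$.  Visibility of an inter-sample interval is taken from its
left sample (step-function semantics); invisible time contributes
neither area nor duration, and nothing is interpolated across
invisible gaps.  Beyond the last sample the curve and flag are
extended as constants to the end of the game.

**QC.**  A coding is usable when the face was visible for at least 8 s
of the Inclusion Period and at least 30 s of the Exclusion Period and
the child was not invisible for more than 30 s in total.  Boundary
semantics are literal: equality passes the two "at least" rules and
passes the "more than 30 s" rule.

**Baseline adjustment.**  Exclusion-period scores are residualized on
inclusion-period scores by OLS with intercept, fitted over the
analysis sample, channel by channel and for the three-channel total.
Residuals have mean zero and are orthogonal to the baseline; if the
baseline is constant the fit degenerates to mean-centering.

**Log scaling.**  Residuals are right-skewed and are compressed with
$\log_{10}(x + 1 - \min x)$, which maps the sample minimum to 0 and is
monotone.  The shift is sample-dependent, so transformed values are
relative to the analysis sample; printed cohort means of
log-transformed scores from other samples are not reproducible from
this transform alone, and no numeric claims are attached to them.

**Contempt.**  Contempt AUCs are bimodal with a dominant no-contempt
peak and are collapsed to an indicator of any (strictly positive)
exclusion-phase contempt.

## Questionnaire and reliability

The 15-item post-game questionnaire (Likert 1–5) contains nine
"after-the-game" and six "during-the-game" items.  Positively phrased
items are reversed ($6 - x$).  Two figurative after-items load below
0.40 and are excluded; the retained items form a six-item
"Negative feelings during the game" scale and a seven-item
"Negative feelings after the game" scale, each scored as the mean of
its recoded items (missing items are dropped from the mean).  The
shipped `item_specs.csv` fixes a defensible phase/polarity layout for
the synthetic instrument; it is a package convention, not a claim
about the original item wording.

Factor structure is examined with principal-axis factoring (iterated
communalities starting at squared multiple correlations) followed by
varimax rotation with Kaiser normalization.  Two numerical choices
deserve note:

* *PAF convergence.*  The communality iteration is sub-linear when a
  near-null factor is extracted; demanding machine-tight tolerances
  then fails on perfectly reasonable data.  The default stopping rule
  is a maximum communality change of $10^{-3}$ (the convention of
  widely used factor-analysis software) with an iteration cap;
  non-convergence is a hard error, and both knobs are arguments.
* *Varimax implementation.*  The rotation is computed by classic
  pairwise Givens sweeps with Kaiser's quartic angle formula, each
  step accepted only if it raises the simplicity criterion.  The
  SVD-update algorithm used by `stats::varimax()` has degenerate
  stationary points at exactly clustered loading patterns (it returns
  such inputs unrotated); the pairwise form does not, and the two
  implementations agree on generic inputs (this is tested).

Internal consistency is Cronbach's alpha on complete cases; inter-coder
reliability is the two-way random-effects, absolute-agreement,
single-measure intraclass correlation ICC(A,1), computed from the
two-way ANOVA mean squares.  Reliability is computed on raw
(pre-residualization) exclusion-phase AUCs: agreement concerns the
coding itself, not a sample-dependent transform.

## Association models

Outcomes and continuous regressors (age, IQ, log AUC scores) are
z-scored; binary and indicator regressors (sex, maternal university
education, the two parental-origin contrasts against the Dutch
reference) stay 0/1, so their coefficients are group differences in
outcome-SD units.  This convention matches the magnitudes of the
published mutually adjusted models; a `standardize_binary` switch
provides the all-z-scored alternative.  Inference is Wald, $t$ with
$n - p$ degrees of freedom, no multiple-testing correction, two-sided
$\alpha = 0.05$.  Sensitivity refits use a Huber M-estimator (tuning
1.345, MAD scale) via `MASS::rlm`; on an exact fit the M-estimator is
the OLS solution and the code returns it directly rather than
iterating on a zero scale.  CBCL broadband scores are sums of 32
(internalizing) or 35 (externalizing) three-level items; up to 25% of
a scale's items may be missing, in which case the observed sum is
rescaled by items/observed, otherwise the score is undefined.

## The synthetic cohort

The generator emulates the study conditions: 4,813 children; covariate
marginals (50.8% girls, age 9.80 ± 0.34 years, 26.6% university-educated
mothers, IQ 101.70 ± 14.97, origin 59.3/9.0/31.7% Dutch/non-Dutch
Western/non-Dutch non-Western); period durations 11.6 ± 6.0 s and
52.4 ± 2.8 s (truncated to [9, 30] and [40, 65] s — without truncation
a quarter of children would have an inclusion period shorter than the
8-s visibility rule and be unscoreable by construction); 10 Hz
sampling.

Three unit-variance latents drive the data: expressivity $E$ (facial
expression), a during-game report factor $R$ and an after-game factor
$A$.  Standardized paths (covariates $\to E$, covariates and
$E \to R$, $R \leftrightarrow A$, $R$ and $E \to$ CBCL latents) carry
the cross-variable structure; residual noise is scaled analytically so
every latent has exactly unit variance, and infeasible path systems
are rejected.

Traces follow an interpretable functional form: a small, loosely
coupled baseline during inclusion; during exclusion an exponential
approach (time constant 18 s) toward a child-specific asymptote that
is lognormal in a channel latent loading on $E$ (weight 0.5; the
sadness–anger latent correlation is a calibrated parameter); a
multiplicative recovery dip $1 - d\,e^{-(t - t_r)/\tau}$ ($d = 0.5$,
$\tau = 2.5$ s) after each toss the participant receives, reproducing
the qualitative time-course shape (rising negative expression, dips
after tosses 15 and 25) that is asserted as a property, not a numeric
target.  Per-channel zero inflation matches the reported expresser
fractions (75.1% sadness, 70.1% anger, 25.5% any contempt; the
contempt latent is independent of $E$, matching its near-zero printed
correlations with the other channels).  Coders observe the latent
curves through a per-(coder, video, channel) lognormal gain plus small
AR(1) tracking noise that is active only while the child expresses,
clipped to the 0–5 range; visibility drops out as a two-state process
(hazard 0.04/s, mean invisible episode 1.5 s), which leaves ≈95% of
children QC-eligible, and analyses run on the eligible subset.

**Calibration.**  The printed study estimates are *estimates*, not
generative truth: Likert discretization, clipping, coder noise, AUC
nonlinearity and scale unreliability all attenuate what the pipeline
recovers.  `calibrate()` therefore treats the printed standardized
coefficients, correlations, alpha and ICC as target estimands and
iteratively adjusts the generating knobs (damped multiplicative
updates; monotone transform-space updates for the alpha and ICC
knobs — item loading via the mean inter-item correlation, coder gain
via $1/\mathrm{ICC} - 1$) until the full pipeline reproduces them.
The shipped `default_config.yaml` is the frozen result of a staged
calibration run (pilot cohorts of 2,000, then full-size cohorts with
increasing replicate counts); its audit table ships as
`calibration_audit.csv`.  Stochastic study-level quantities are
evaluated as means over seeded replicate cohorts of 4,813 children —
20 replicates in the reproduction script, 40 in the package's own
recovery tests, where the indicator-contrast coefficients (per-cohort
SD ≈ 0.03) need the extra replicates to resolve a 0.01 check.

**What passing does and does not show.**  The generator reproduces the
study's *statistical structure* (marginals, factor structure,
reliability levels, standardized associations) under known ground
truth, so parameter-recovery checks validate the scoring and inference
machinery end to end.  It does not emulate real coder behavior beyond
a gain-plus-noise model, real visibility patterns, attrition or item
nonresponse, and its trace dynamics are an invented functional form
constrained only by the qualitative time-course features.  Two known
fidelity gaps: the shared coder gain couples the two periods, so the
synthetic inclusion–exclusion AUC correlation (≈0.45) exceeds the
reported 0.15–0.22; and the union of expresser indicators implies
≈94% of children showing any emotion versus the reported 98.4%.
Neither quantity enters a calibration target or acceptance check.

**Seeds.**  All randomness flows from one integer seed per call;
cohorts are fully reproducible.  Seeds are consumed from a single
stream — passing the *same* seed to two different samplers replays the
same underlying uniforms and couples their draws, so compose stages
through `simulate_cohort()` (one stream) or use distinct seeds.

## Degenerate inputs and tie-breaks

Zero visible time in a scoring window is an error (such children are
QC-excluded upstream).  A constant baseline falls back to
mean-centering; zero between-subject variance makes the ICC undefined
(error); zero total variance makes alpha undefined (error).  In the
paired inclusion/exclusion contrast, identical period scores return
$t = 0$, $p = 1$; note that under the shift-invariant log transform a
constant raw-score shift *is* the identical case.  Item assignment
uses the largest absolute rotated loading with a 0.40 threshold;
factor columns are sign-flipped so each column's loading sum is
positive and ordered by explained variance.
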