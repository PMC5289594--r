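---
title: "Methods: simulating the impact of network meta-analysis choices on cost-effectiveness results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the impact of network meta-analysis choices on cost-effectiveness results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package answers

Decision-analytic cost-effectiveness (CE) models for chronic disease combine
many parameters — transition probabilities, event probabilities, costs,
utilities — each typically obtained by meta-analysis of several trials. When
more than two interventions are in play, the analyst must choose a mixed
treatment comparison (MTC) method, and that choice propagates into the final
incremental QALYs, costs, ICERs and acceptability curves. `nmahesim` builds a
fully synthetic world in which the truth is known, samples trial networks
from it, pools them with five competing methods, pushes each pooled
parameter set through the same Markov CE model, and scores every method on
coverage, statistical power, bias and mean absolute deviation (MAD).

The pipeline has five steps: (1) build a superpopulation whose mean outcomes
define the truth; (2) sample two-arm trials; (3) pool trial parameters by
each meta-analysis method; (4) run the probabilistic CE model per method;
(5) repeat and score.

# The disease world

## Structure

Patients move monthly between four stages — Moderate, Severe, Very Severe and
absorbing Death — and can additionally suffer a *temporary event* in any
alive cycle (symptoms worsen briefly: a cost and a utility decrement, no
stage change, and no effect on later transitions). Twelve effect-bearing
parameters drive the dynamics: three progression probabilities (M→S, M→VS,
S→VS), three improvement probabilities (S→M, VS→S, VS→M), three death
probabilities (M→D, S→D, VS→D) and three per-stage event probabilities.
The horizon is 12 monthly cycles (one year), no discounting; the stage at
cycle 1 is the starting stage, life years count alive cycles / 12, and no
half-cycle correction is applied.

## Reference disease progression and additive modification

A *reference disease progression* (RDP) gives each parameter's monthly
probability for an untreated base-case patient (male, aged 18–34, developed
country, BMI < 25, non-smoker). Patient characteristics and interventions
modify the RDP *additively* in probability points, then the result is
clamped to [0, 1]; when the three competing exits of a stage sum above one
they are renormalized proportionally (the remainder is the stay
probability). The canonical worked example, hard-anchored in the defaults:
Severe→Death is 10% (RDP) − 2 (female) + 4 (age 35–64) − 3 (New
Intervention) = 9%.

The four fictitious interventions follow the qualitative description of the
study design: *No Intervention* does nothing and costs nothing; *Old
Intervention* reduces events and mortality for a one-off €250; *Usual Care*
slows progression at €60/cycle; *New Intervention* slows progression, helps
improvement, reduces events (and, per the worked example, mortality) at
€350/cycle. Per-cycle intervention costs accrue only while alive; the
one-off cost accrues at cycle 1.

## Calibration of the shipped defaults

The exact numeric content of the original reference-progression table is not
available to this package, so the default `disease_spec()` is a calibrated
stand-in. Calibration minimized the weighted squared error between targets
taken from the study's reference-outcome table — per-intervention QALYs,
total costs, the Usual/New stage-occupancy and event rows, and the six
pairwise ICERs implied by them — and the *exact* expectation of the
microsimulation, computed by enumerating the 72 covariate classes (gender ×
age band × country × BMI category × smoking), running the deterministic
cohort chain per class and weighting by the theoretical class probabilities
(`expected_outcomes()`). Free parameters were the 11 non-anchored RDP
values, per-stage intervention deltas, and the stage maintenance costs and
utility weights; characteristic modifiers were fixed a priori at plausible
magnitudes consistent with the scenario-table footnotes (older patients,
smokers and the obese deteriorate faster, have more events, cost more and
have lower utility — with the cost/utility channel deliberately strong,
since that is what the footnotes emphasize about less healthy trial
populations). Optimized values were rounded to 0.1 probability points and
frozen in `R/disease_defaults.R`; the calibration scripts live in
`tools/`. The
acceptance suite asserts the calibration bands the build contract defines
(headline QALY difference within ±0.01; ICERs within ±15%), not an exact
reproduction: a user-supplied transcription of the original table, passed as
a JSON file to `read_disease_spec()`, supersedes the defaults block by
block and enables exact reproduction.

Costs and utilities also carry characteristic modifiers (e.g. smokers cost
€30/cycle more and lose 0.03 utility). This serves two purposes: it
realizes the "worse average health ⇒ higher maintenance costs, lower
quality of life" property that biased subpopulations must exhibit, and it
gives arm-level cost/utility estimates genuine sampling variance, without
which pooling them would be degenerate.

# What the generator emulates — and what it does not

The superpopulation (default 50,000 patients) is simulated once per
intervention with the *same* patients, so between-intervention differences
contain no roster noise ("moderately independent simulations"). Sampled
trials re-use the stored trajectories; a patient can appear in several
trials (superpopulation framing) but arms within a trial are disjoint.
Heterogeneity scenarios bias specific trials by *tilting* their sampling
weights towards subpopulations rather than excluding anyone: patients
flagged as worse-health (age > 55, smoker, or BMI > 30) are over-sampled by
a factor of two, the extreme stress scenario squares the tilt, and the
younger/older filters tilt on the age tails. The original design describes
directions, not magnitudes; the tilt strength was calibrated, together with
the disease world, against the study's reported qualitative behavior
(biased trials shift parameter estimates by a few percent, yet no method's
coverage drops below 90% outside the extreme scenario). A hard-cutoff
filter — the obvious alternative — produces far stronger selection than
those reported properties allow.

A green test therefore establishes that the *methods* behave as claimed in
a world with the stated structure — it does not establish anything about
real trial data: there is no dropout, no measurement error, no unequal arm
sizes, no inconsistency mechanism beyond covariate imbalance, and the
evidence network is deliberately "regular" (all six contrasts directly
observed; slots 1, 6, 8 fixed to Old-vs-No, New-vs-No, New-vs-Usual; the
remaining six slots assigned so that every pair has direct evidence).

# Trial summaries

Monthly data collection makes the natural exposure unit the *at-risk
patient-cycle*: for a transition, cycles 1–11 spent in the origin stage; for
an event, alive cycles 1–12 in the stage. Arm-level counts (r, n) per
parameter feed every method. The trial-level effect is
ln RR = log((r1/n1)/(r0/n0)) with variance 1/r1 − 1/n1 + 1/r0 − 1/n0; 0.5
is added to all four cells when any cell is zero or complete, and the
estimate is flagged. Arm-level means and standard errors of stage-wise
maintenance cost, stage-wise utility, event cost and event decrement are
collected for the absolute parameters.

# The five pooling methods

* **DIRECT** — DerSimonian–Laird (DL) random-effects pooling of the trials
  that compare the contrast head-to-head. The between-study variance is the
  moment estimator with the zero branch when Q < S − 1; a single study is
  returned as-is with tau² = 0 (the estimator is 0/0 at S = 1).
* **SONG** — adjusted indirect comparison: for every intermediate
  intervention j with direct evidence on both legs, the indirect estimate is
  the difference of the DL-pooled legs with summed variances; the direct
  estimate and all indirect estimates are then DL-pooled as if each were a
  single trial.
* **PUHAN** — fixed-effect logistic regression on the records reconstructed
  from the summary tables (one Bernoulli unit per at-risk patient-cycle),
  with treatment dummies and study dummies; fitted equivalently via
  aggregated binomial counts (identical maximum likelihood). The treatment
  coefficient is a log odds ratio.
* **GLMFE / GLMRE** — Bayesian binomial-logit network model:
  r\_sk ~ Binomial(p\_sk, n\_sk), logit(p\_sk) = mu\_s (+ trial effect).
  Fixed effects impose one d per treatment; random effects draw the
  trial-level effect from N(d\_t − d\_b, sigma²) with a *common* sigma²
  across contrasts. Priors: Beta(0.5, 0.5) on each trial's baseline
  probability (transformed to the logit scale with its Jacobian),
  N(0, 1e8) on treatment effects, sigma ~ U(0.001, 10). Sampling is an
  adaptive component-wise random-walk Metropolis (Rcpp) with the trial
  effects in a *non-centered* parametrization (delta = d + sigma·z) — the
  centered form mixes badly when the data carry little heterogeneity and
  silently understates the treatment-effect variance. Defaults: 2 chains,
  5,000 burn-in, 10,000 retained draws; convergence is assumed for the
  fixed schedule, mirroring the study's own position, and no diagnostic
  gates the result. The test and acceptance runs use a reduced fixed
  schedule (1,000 burn-in, 2,000 retained) for runtime only.

  The random-effects estimate handed to the CE model is the posterior
  *predictive* trial-level effect N(d, sigma²), not the posterior of the
  mean effect d: the effect operating in the model's target population is
  itself a draw from the between-trial distribution. This is what makes the
  random-effects model the most conservative of the five — without it the
  two Bayesian variants are nearly indistinguishable.

All relative effects are reported as ln RR. Odds ratios from the regression
and Bayesian methods are converted via RR = OR / (1 − p0 + p0·OR), where p0
is the DL-pooled comparator-arm risk: draw-by-draw for posterior samples,
delta method for frequentist point estimates. Absolute quantities (baseline
probabilities from comparator arms, costs, utilities) are DL-pooled from
arm-level means with squared standard errors as within-trial variances; a
small SE floor (0.1% of the largest mean) guards against numerically zero
arm variances. Frequentist intervals are Wald ±1.96·SE; Bayesian intervals
are 2.5/97.5 posterior percentiles.

# The cost-effectiveness model

Step 4 uses a deterministic Markov *cohort* model (not a re-microsimulation):
the population starting vector (5/8, 2/8, 1/8, 0) is evolved under the
pooled comparator probabilities, and under the comparator probabilities
multiplied by the drawn relative risks (clamped at 1, exits renormalized)
for the treatment arm. Population heterogeneity enters only through the
pooled parameters, which is exactly how such models are built in practice.
The probabilistic sensitivity analysis (default 1,100 iterations) draws
ln RR ~ Normal(point, variance), baseline probabilities and utilities from
moment-matched Beta distributions, costs from moment-matched Gamma
distributions; fixed intervention prices are not drawn. When Beta moment
matching is infeasible (SE² ≥ m(1 − m)) a clamped normal is substituted.
Both arms share every draw of the common parameters within an iteration, so
incremental outcomes isolate the treatment effect. CEACs report the
fraction of iterations with positive net monetary benefit across a
willingness-to-pay grid.

# Scoring

Per repetition, every method pools the *same* sampled network and the PSA
uses the same seeds, so method differences are attributable to the methods.
Coverage is the fraction of repetitions whose 95% interval contains the
truth; power the fraction excluding the null (0 on difference scales, RR = 1
for parameters); bias the mean signed deviation and MAD the mean absolute
deviation, both expressed relative to the truth in percent (parameter-level
metrics are computed on the RR scale; a zero truth falls back to the
absolute scale, flagged). Summary bands follow the study's conventions:
uncertainty is *under*estimated below 90% coverage and *over*estimated above
98%; bias bands 1–2% and > 2%; MAD bands 4–7% and > 7%.

# Numerical and design choices worth knowing

* Additive deltas clamp to [0, 1]; competing exits renormalize
  proportionally; event probabilities clamp independently.
* Exposure denominators are patient-cycles, not patients (see the ledgered
  open question): monthly collection implies per-cycle hazards and keeps the
  PUHAN and GLM likelihoods structurally identical.
* One master seed fans out through `derive_seed()` (a small string-hash
  splitter, always < 2^31) into population / per-intervention /
  per-repetition / per-trial / PSA substreams; any component can be re-run
  in isolation, and identical invocations produce byte-identical artifacts.
* The vectorized PSA cohort engine is verified against the scalar
  `run_markov()` to 1e-12 in the test suite; the class-weighted expectation
  `expected_outcomes()` is verified against the microsimulation within
  Monte-Carlo error.
* Single-trial networks drop the (constant) study dummy; separation-prone
  cells receive the same flagged 0.5 correction everywhere.

# Known limitations

* The default world is a calibrated stand-in, not the original supplementary
  table; headline outcomes agree within the stated bands, but individual
  RDP entries need not match, so parameter-level truths differ from the
  original study's even where the headline CE quantities agree. In
  particular, the *bias geometry* of heterogeneous scenarios (how far
  biased trials push the estimated cost-effectiveness towards a
  willingness-to-pay threshold) depends on modifier magnitudes the stand-in
  cannot pin down: the calibrated world keeps every method's coverage above
  90% in scenarios 1–7, and accepts that the scenario-7 median CEAC at
  €30,000/QALY lands above the originally reported mid-fifties value. The
  acceptance suite reports this honestly rather than re-tuning the world.
* The Metropolis sampler is adequate for these small binomial-logit
  networks but is not a general-purpose MCMC engine; with the reduced test
  schedule, Monte-Carlo error on posterior means is of order 0.01–0.02 on
  the ln OR scale.
* Network inconsistency testing, MCMC convergence diagnostics, discounting,
  horizons other than 12 cycles, > 4 interventions and > 2 arms per trial
  are out of scope by design.
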