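---
title: "Signature-shift analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-shift analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigshift)
```

This vignette is the package's account of its statistical machinery: what
each stage assumes, which parameters matter, how the synthetic-trial
generator is built, and where the method's known limitations lie.

## The problem

Inclusion body myositis progresses slowly, so a short single-arm trial
cannot rely on arm-vs-arm contrasts. The design analysed here instead uses
a lead-in phase: every patient is observed untreated for 16 weeks (baseline
to week 16) and then treated for 16 weeks (week 16 to week 32), with muscle
biopsies at all three time points. The untreated phase is each patient's
own comparator. The analytic question is whether treatment moved a
patient's metabolome *relative to a disease signature* — and whether that
molecular movement tracks clinical outcomes measured at weeks 0, 16, 32 and
48.

## Normalization

`normalize_intensities()` applies, in a fixed order:

1. division of each sample's intensities by its protein concentration
   (mg/mL, per-sample scalar from a BCA assay) — corrects for input
   material;
2. log2 transform, with zero or negative intensities set to missing first.
   No pseudocount is used: pseudocounts distort fold changes exactly where
   abundances are low, and downstream statistics all tolerate missingness
   by pairwise-complete deletion;
3. per-sample median centering (target 0). Any per-sample multiplicative
   scale — including the protein factor itself — is a constant shift on the
   log2 scale and is removed exactly by this step, which the test suite
   asserts as an invariance.

The order "log, then median" is a deliberate choice; centering on the raw
scale would not remove multiplicative sample effects. Exclusions (the
package defaults to removing epinephrine, an anaesthetic carry-over in
biopsy material whose abundance is non-physiological) are applied *before*
normalization so that an excluded metabolite can never influence a sample
median; the audit trail records the order.

## The disease signature and the moderated test

The signature is the vector of per-metabolite log2 fold changes,
case minus control group means of centered log2 values, using each case's
baseline sample only. With 15 cases against 5 controls, per-metabolite
variance estimates are unstable, so the default test moderates them:
per-metabolite sample variances \(s_m^2\) (pooled, \(d\) degrees of
freedom) are assumed drawn from a scaled inverse-chi-square prior with
hyperparameters \((d_0, s_0^2)\). Marginally \(s_m^2/s_0^2 \sim F(d, d_0)\),
and matching the first two moments of the observed variance distribution
gives

\[ d_0 = \frac{4Rd + 2d - 4}{Rd - 2}, \qquad
   s_0^2 = \bar{s^2}\,\frac{d_0 - 2}{d_0}, \qquad
   R = \widehat{\mathrm{Var}}(s^2)/\bar{s^2}^2 . \]

If \(Rd \le 2\) the variances are no more dispersed than a single
chi-square allows, no finite \(d_0\) fits, and the prior degenerates to a
point at the pooled mean variance (\(d_0 = \infty\)); if the solution falls
at or below 4 the matched variance moment does not exist and \(d_0\) is
clamped just above 4. The moderated statistic uses the posterior variance
\(\tilde{s}^2 = (d_0 s_0^2 + d s_m^2)/(d_0 + d)\) with a \(t_{d + d_0}\)
reference. `prior_df = 0` recovers the ordinary pooled t exactly;
`prior_df = Inf` shrinks every variance to \(s_0^2\); both limits are
tested, and the full construction is checked against an independent
straight-line implementation and against limma's empirical-Bayes fit
(which estimates the prior on the log-variance scale, so agreement is close
but not bit-identical).

Multiplicity is handled per analysis family: one Benjamini–Hochberg
adjustment across metabolites within a signature, and one across
metabolites of Fisher-combined p-values
(\(X = -2\sum_k \ln p_k \sim \chi^2_{2k}\)) when two comparisons are
labelled jointly.

Group separation is summarized on the first principal component of the
samples (per-metabolite centering only, no unit-variance scaling — inputs
are already median-centered, and scaling would up-weight noise-dominated
metabolites). The default test is the two-sided variance-ratio F on PC1
scores, reflecting that case heterogeneity — not merely a mean shift — is
the salient feature; a one-way ANOVA on PC1 scores is available via
`method = "anova"` since the construction is not uniquely determined by the
phrase "F-test on PC1".

## The rho score and its jackknife interval

Each patient × phase log2FC vector (later minus earlier centered log2
values, metabolites present at both endpoints) is correlated against the
signature with Spearman's ρ — a rank statistic, so the score is invariant
to any monotone distortion of either vector and robust to heavy-tailed
fold changes. The confidence interval is a delete-one jackknife over
metabolite *pairs*, computed on the Fisher-z scale (the variance-
stabilizing choice for correlations) with a normal-theory interval around
the full-sample z, back-transformed and clamped to \([-1, 1]\). Pairs whose
removal leaves a constant vector are skipped; if fewer than 80% of
pseudovalues survive, the interval is refused rather than reported noisy.
For tie-free vectors all \(n\) leave-one-out correlations are computed in
closed form from rank updates (removing a pair shifts every higher rank
down by one), which the suite verifies against the naive loop exactly.

Monte-Carlo calibration (500 Gaussian-copula samples of 150 pairs, true
Spearman ρ = 0.5) puts the empirical coverage of the 95% interval at
approximately 0.95–0.96; the acceptance suite requires \([0.90, 0.98]\).

A patient is a **responder** when the lead-in and treatment intervals are
disjoint *and* the treatment interval lies entirely below — i.e. the
within-patient change is significant and points away from the disease
profile. The directionality requirement is this package's addition (the
disjointness rule alone would also call a patient who moved *toward* the
disease a "responder"); `directional = FALSE` restores the plain
no-overlap rule. The minimum common-metabolite threshold (default 10)
marks scores unusable rather than silently noisy.

## Severity stratification

Heckmatt echointensity grades (ordinal 1–4) for flexor digitorum
profundus, vastus lateralis and rectus femoris are reduced to a sum score
by taking the bilateral maximum per muscle and summing (range 3–12).
Severe disease is a sum score strictly above 10 *with* atrophy in at least
one muscle; the atrophy condition enters only the label, never the score,
and can be dropped with `require_atrophy = FALSE`.

The phase × severity analysis is a classical two-way mixed ANOVA — phase
within subject, severity between — computed by the univariate
decomposition through `aov` with a subject error stratum. With only two
within-subject levels, sphericity holds trivially and no correction is
applied. Tukey HSD over the four cell means uses `emmeans` on the fitted
stratified model. The response is the per-phase rho by default; because the
design is balanced two-level, the equivalent one-way ANOVA on per-subject
change scores (`response = "change"`) yields the identical interaction
p-value, which the suite asserts. The leave-one-out sensitivity analysis
refits with each subject removed and flags a subject as influential when
the interaction p-value crosses the 0.05 boundary in either direction —
the same diagnostic that, in the motivating trial, moved the interaction
from significant to non-significant upon removal of one strong responder.

## Clinical outcome models

Both longitudinal models are REML fits with `lme4`:

* treatment model: `outcome ~ 1 + Treatment*Time + (1 + Time | subject)`,
* rho model: `outcome ~ 1 + rho(t)*Time + (1 + Time | subject)`,

with Time coded as the visit index in 16-week units (weeks 0/16/32/48 →
0–3) and Treatment an indicator for the on-drug visits (weeks 32, 48). The
time-varying covariate rho(t) carries the lead-in score at weeks 0 and 16
and the treatment score at weeks 32 and 48. Fixed-effect p-values are Wald
z tests; with around a dozen subjects these are mildly anti-conservative
(Monte-Carlo coverage of the 95% interval for the planted rho × Time
coefficient sits near 0.88–0.94 rather than 0.95), which is disclosed here
rather than corrected, as the Wald convention matches the reporting style
the pipeline reproduces. If the random intercept-and-slope fit is singular
or fails the optimizer's checks, the model automatically refits with a
random intercept only and records the fallback; a fit that is *still* on
the variance boundary keeps its estimates but withholds p-values.
`lmer`'s gradient heuristics flag exact zero-noise fits as suspect even
though the optimizer converges, so final convergence status follows the
optimizer's return code, not the heuristic warnings.

`predict_trajectory()` produces population-level predictions (random
effects at zero) for hypothetical rho profiles — e.g. a patient holding the
study's highest observed score versus one who drops to the lowest after
week 16 — with delta-method bands from the fixed-effect covariance.
`paired_phase_test()` covers the companion analysis of per-subject lead-in
versus treatment changes with a paired t-test, reporting p = 1 with a
degeneracy flag when every difference is zero.

Subjects missing a phase score are dropped with an audit entry; week-48
records missing for some outcomes are simply absent rows, handled by the
likelihood without imputation.

## The synthetic-trial generator

`generate_trial()` emulates the trial's structure with planted truth:

* **Cohort**: 15 cases (muscle biopsies at weeks 0/16/32), 5 muscle and 10
  serum controls measured once, 211 muscle metabolites with 124 shared with
  serum — the motivating cohort's dimensions, all configurable.
* **Abundances**: per-metabolite baseline log2 abundance ~ Normal(10, 2) —
  a typical LC-MS dynamic range; arbitrary but fixed.
* **Signature**: a dysregulated fraction (default 0.3) of metabolites
  receives large effects ~ Normal(0, 2 log2 units); the rest receive small
  background effects at 5% of that scale, so the planted signature is
  tie-free in rank — real case-control metabolomes are dense in small
  effects, and exact zeros would make rank targets ill-defined. Severe
  subjects' effects are amplified by a configurable factor (default 1.5),
  encoding a severity-accentuated signature. A zero-effect configuration
  (`signature_effect_sd = 0`) plants exact nulls for type-I-error checks.
* **Phase changes**: each subject × phase has a target Spearman ρ against
  the signature. The change vector is built on the Gaussian-score scale:
  the signature's ranks are transformed to normal scores \(z_s\) and mixed
  as \(\rho_P z_s + \sqrt{1-\rho_P^2}\,\varepsilon\) with
  \(\rho_P = 2\sin(\pi\rho_S/6)\), the Gaussian-copula Pearson weight whose
  population Spearman equals the target. The orthogonal budget
  \(\sqrt{1-\rho_P^2}\) *includes* the measurement noise of the two
  endpoint samples, so the target refers to the observed delta, not a
  latent one; the change amplitude (default 1 log2 unit) is raised
  per-subject when an extreme target needs more headroom over the noise.
  Against the planted signature this construction is empirically unbiased
  (regression of realized on target ρ ≈ 1.00).
* **Targets**: lead-in targets scatter Normal(0.03, 0.25) across subjects —
  a stable lead-in with realistic heterogeneity; responders (default
  fraction 1/3, assigned mild-first, mirroring the observation that
  response concentrates in milder disease) additionally shift their
  treatment target by `responder_shift` (default −0.8, the scale of the
  strongest observed within-patient swing, ~0.5 → −0.45).
* **Ultrasound**: grades are drawn so severe subjects land above the
  sum-score cutoff with atrophy and mild subjects below it.
* **Clinical outcomes**: generated from the planted linear mixed model with
  subject-level random intercepts and slopes, using the phase targets as
  the rho covariate. Defaults plant an IBM-FRS-like outcome
  (intercept 29, slope −0.3 per 16 weeks, rho × Time −3.32, residual SD 1,
  random-effect SDs 4 and 0.5) and an m-TUG-like outcome with a positive
  rho × Time of 1.95.
* **Determinism**: one RNG stream seeded once per trial, drawn in a fixed
  order; the same seed reproduces every matrix, annotation and outcome
  byte-identically.

What the generator does *not* emulate: LC-MS peak shapes, retention-time
drift, adducts, batch structure, QC-pool drift, or informative missingness
(an optional uniform dropout flag exists). Passing recovery tests on this
generator therefore demonstrates correctness of the statistical machinery
under the trial's design, not robustness to instrument artefacts.

## Numerical choices and degenerate inputs

* Ties: average ranks everywhere; missingness: pairwise-complete deletion.
* Fisher z is clamped at |ρ| = 1 − 10⁻¹²; intervals are clamped to [−1, 1].
* p = 0 inputs to Fisher combination are clamped to the smallest positive
  double with a warning (the log would otherwise be undefined).
* Constant vectors make a rank correlation undefined and raise errors
  naming the condition; an all-equal rho table short-circuits the ANOVA to
  F = 0, p = 1.
* All-zero samples are rejected by name during normalization (no defined
  median).
* The rho model refuses a rho covariate that is constant across subjects
  (rho × Time would be collinear with Time) and names the degeneracy.

## Problem sizes used by the tests

The acceptance suite simulates at the sizes its properties are stated for:
500 replicates for jackknife coverage (150 pairs), 200 trials each for
responder operating characteristics (200 metabolites), mixed-model recovery
(12 subjects, 4 visits), severity-interaction power, lead-in null
stability, and moderated-test size (211 metabolites, 15 vs 5 samples). The
full suite runs in a few minutes on one CPU.

Two framing notes on those tests. The mixed-model recovery test supplies
the generator's planted phase targets as the rho covariate, isolating the
estimator under test; when the covariate is instead estimated by the full
projection pipeline, the finite precision of the estimated signature
attenuates the realized rho scores multiplicatively (regression slope of
realized on target ≈ 0.88 at the default noise level), which inflates the
recovered rho × Time coefficient by the reciprocal factor — an
errors-in-variables effect inherent to using an estimated covariate, worth
remembering when interpreting the real analysis. And the severity-power
test configures the responder set to be exactly the mild-moderate class,
the literal reading of "response confined to mild disease".

## Known limitations

* The lead-in delta and the disease signature share the baseline samples,
  so their estimation errors are negatively coupled; under a drift-free
  null the cohort-level lead-in-vs-signature correlation is slightly
  negative (≈ −0.03 to −0.09 across seeds) rather than exactly zero. The
  same coupling exists in the real analysis.
* Wald z inference in the mixed models is mildly anti-conservative at
  n ≈ 12 subjects (see above).
* The jackknife CI treats metabolites as exchangeable pairs; correlated
  metabolite blocks (pathways) will make intervals somewhat narrow.
* The severity ANOVA treats estimated rho scores as known responses; their
  estimation error is small relative to between-subject spread at the
  default panel size (~200 metabolites) but would matter for small panels.
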