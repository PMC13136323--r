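# sigshift

Signature-shift analysis for single-arm lead-in/crossover trials with
longitudinal omics readouts, built around the design of a pioglitazone trial
in inclusion body myositis (IBM): every patient serves as their own control,
with a 16-week observation phase before treatment and muscle biopsies at
baseline, week 16 and week 32.

The package is for analysts of small interventional trials who want to ask,
per patient, *did the treatment move this patient's molecular profile toward
or away from the disease state?* — and then relate that molecular answer to
clinical outcomes.

## The method

1. **Normalization.** Raw metabolite intensities are divided by each
   sample's protein concentration, log2-transformed (zeros treated as
   missing) and median-centered per sample.
2. **Disease signature.** The per-metabolite case-vs-control log2 fold
   change, log2FC = mean(case) − mean(control) on the centered log2 scale,
   tested with a moderated t-statistic: per-metabolite variances are shrunk
   toward a moment-matched empirical-Bayes prior, t = log2FC / √(s̃²(1/n₁ +
   1/n₂)) with s̃² = (d₀s₀² + d s²)/(d₀ + d), and Benjamini–Hochberg FDR
   across metabolites.
3. **Signature-shift score.** For each patient and phase (lead-in:
   baseline→W16; treatment: W16→W32), the metabolite-wise log2FC vector is
   correlated against the disease signature with Spearman's ρ. Positive ρ =
   the patient moved *toward* the disease profile; negative ρ = toward
   controls. A delete-one jackknife over metabolite pairs on the Fisher-z
   scale gives each ρ a 95% confidence interval.
4. **Responder classification.** A patient is a metabolic responder when
   the lead-in and treatment CIs do not overlap and the treatment interval
   lies below the lead-in interval.
5. **Severity stratification.** Heckmatt ultrasound grades (1–4, bilateral
   maximum over FDP/VL/RF) are summed; a sum score > 10 with atrophy defines
   severe disease. A two-way mixed ANOVA (phase × severity) with Tukey HSD
   and a leave-one-out sensitivity analysis tests whether response depends
   on severity.
6. **Clinical outcomes.** Linear mixed models
   `outcome ~ 1 + Treatment*Time + (1 + Time | subject)` and
   `outcome ~ 1 + rho(t)*Time + (1 + Time | subject)`, where rho(t) is the
   lead-in score at weeks 0/16 and the treatment score at weeks 32/48; the
   rho × Time coefficient is the headline link between metabolic shift and
   clinical trajectory, and `predict_trajectory()` turns it into
   counterfactual visit-level predictions.

A synthetic-trial generator (`synthetic_config()` / `generate_trial()`)
plants all of these quantities — signature, per-patient phase targets,
responder flags, severity classes, mixed-model coefficients — so that every
stage has a parameter-recovery test against known truth.

## Worked example

```r
library(sigshift)

trial <- generate_trial(synthetic_config(seed = 7))
x     <- normalize_intensities(trial$muscle)
sig   <- estimate_signature(x, trial$annotation)
head(sig[order(sig$fdr), ], 3)
#>    metabolite log2FC     t        p      fdr n_case n_control
#> 19     MET019  -3.74 -11.6 4.43e-11 1.35e-09     15         5
#> 21     MET021   4.91  11.4 5.96e-11 1.35e-09     15         5
#> 62     MET062   3.76  12.1 1.77e-11 1.35e-09     15         5

rt <- rho_score_table(patient_deltas(x, trial$annotation), sig)
head(rt, 4)
#>   subject_id     phase   rho ci_low ci_high n_used usable
#> 1        P01   lead_in -0.26  -0.38   -0.12    211   TRUE
#> 2        P01 treatment -0.83  -0.88   -0.77    211   TRUE
#> 3        P02   lead_in -0.45  -0.56   -0.32    211   TRUE
#> 4        P02 treatment -0.84  -0.88   -0.77    211   TRUE

sum(responder_table(rt)$responder)
#> [1] 5

an <- severity_anova(rt, severity_classes(trial$ultrasound))
sprintf("phase x severity: F = %.2f, p = %.4f", an$interaction_F, an$interaction_p)
#> [1] "phase x severity: F = 7.58, p = 0.0164"

fit_rho_model(trial$clinical, "IBM_FRS", rt)
#> mixed_model_result: IBM_FRS (rho model, intercept_and_slope, converged)
#>          term   estimate        se             p
#> 1 (Intercept) 30.2005112 1.2081609 6.574941e-138
#> 2       rho_t  0.2407495 1.2900773  8.519615e-01
#> 3        time -0.2615276 0.2092259  2.113079e-01
#> 4  rho_t:time -3.7440724 0.5151558  3.652671e-13
```

The first table is the disease signature (strongest dysregulated
metabolites); the second gives each patient's per-phase shift score with its
jackknife CI (P01 and P02 both moved sharply toward the control profile
under treatment); five of the fifteen synthetic patients are called
responders; the interaction test shows the response is concentrated in
mild-moderate disease; and the negative `rho_t:time` estimate means that
staying metabolically disease-like predicts a faster IBM-FRS decline.

File-based trials work the same way through `simulate_trial()`,
`run_config()` and `run_pipeline()`, which write per-stage TSV outputs and a
checksummed JSON run report.

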