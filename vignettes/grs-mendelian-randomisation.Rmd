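---
title: "One-sample Mendelian randomisation with unweighted genetic risk scores"
author: "grsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample Mendelian randomisation with unweighted genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmr)
```

## The problem

Observational associations between dispositional traits (neuroticism,
educational attainment, habitual physical activity) and job satisfaction are
confounded: unmeasured factors plausibly drive both, and reverse causation
cannot be excluded. Mendelian randomisation (MR) sidesteps both problems by
using genetic variants as instrumental variables: alleles are assorted at
conception, so a genetic risk score (GRS) that predicts an exposure is —
under the instrumental-variable assumptions — independent of the confounders
of the exposure–outcome relation and affects the outcome only through the
exposure.

`grsmr` implements the full individual-level (one-sample) analysis: building
unweighted GRSs from dosage data with per-variant quality control,
questionnaire phenotype derivation, observational least squares, univariable
two-stage least squares (TSLS), multivariable MR (MVMR), a per-variant
instrument-validity screen, weak-instrument diagnostics (first-stage F and
the Sanderson–Windmeijer conditional F), and analytic power. Because
individual-level biobank data are access-restricted, the package ships a
synthetic-cohort generator that reproduces the *statistical structure* of
such a study, so the whole pipeline is testable end to end.

## The estimators

Write $y$ for job satisfaction, $x$ for a measured exposure z-score, $g$ for
its GRS and $C$ for covariates (age, sex, assessment centre, Townsend
deprivation index; optionally log BMI).

**Observational OLS** fits $y = \alpha + \beta x + C\gamma + \varepsilon$
with classical standard errors ($n-k$ divisor). With an unmeasured
confounder $U$ loading $c_x$ on the exposure and $c_y$ on the outcome, the
OLS slope converges to $\beta + c_x c_y$ — biased.

**Univariable TSLS** regresses $x$ on $(g, C)$, then $y$ on the fitted
$\hat{x}$ and $C$. The point estimate equals the textbook instrumental
variable estimator; in the just-identified case without covariates it is
the Wald ratio $\mathrm{cov}(g,y)/\mathrm{cov}(g,x)$ (a machine-precision
test in the suite). Standard errors apply the usual IV correction: the
residual variance is computed from $y - X\hat\beta$ with the *observed*
exposure, not the fitted values, divided by $n-k$ (a divisor of $n$, as some
econometrics software defaults to, is available via `model_spec(dof =
"n")`). Confidence intervals are normal-approximation $\pm 1.96\,SE$;
p-values are two-sided from the t distribution with $n-k$ degrees of
freedom.

**MVMR** estimates the *direct* effect of each exposure conditional on the
others. The default `"own"` instrumenting mode follows the multi-stage
construction: one first-stage regression per trait using only its own GRS,
then a single second-stage regression of the outcome on all three fitted
exposures together, with covariates in every stage and IV-corrected
standard errors. The `"all"` mode is textbook 2SLS with the full instrument
set. When the cross first-stage coefficients are exactly zero the two modes
coincide; with trait-specific instruments and exposure correlation induced
environmentally (as the generator does), the cross coefficients are zero in
population, and the suite checks that the two modes agree within
Monte-Carlo error.

**Instrument strength.** The first-stage F is the partial F of the
instrument block in $x \sim g + C$ versus $x \sim C$; for a single
instrument it equals the squared first-stage t statistic exactly. For MVMR
the Sanderson–Windmeijer conditional F measures the strength of each
exposure's instruments *given the other exposures*: the exposure is first
residualised on the other exposures using an IV fit with the full
instrument set, the residual is regressed on all instruments and
covariates, and the instruments' joint F is reported with numerator degrees
of freedom (number of instruments − number of exposures + 1). With one
exposure this reduces algebraically to the standard F. Fits print a
prominent flag when F < 10.

**Analytic power** uses the standard non-centrality approximation for MR
with a continuous outcome: $NCP = n R^2_{gx} \beta^2$ in standardised
units and
$\text{power} = 1 - \Phi(z_{1-\alpha/2} - \sqrt{NCP}) + \Phi(-z_{1-\alpha/2} - \sqrt{NCP})$.
At $\beta = 0$ this returns exactly $\alpha$. The approximation is mildly
optimistic at modest instrument strength: at $n = 2{,}000$, $R^2 = 1\%$,
$\beta = 0.2$ (first-stage F ≈ 20) the analytic value is 0.146 while the
empirical TSLS rejection rate is near 0.13 — the suite's Monte-Carlo check
allows for this within its binomial tolerance.

```{r power}
mr_power(n = 73296, r2_gx = 0.0114, beta_std = 0.30)
mr_min_n(0.8, r2_gx = 0.0114, beta_std = 0.30)
```

## What the synthetic cohort emulates

`sim_config()` fixes the generative model; `simulate_cohort()` draws from
it. The defaults are the study conditions the package targets:

* **Genotypes.** Three trait-specific panels (136, 70 and 22 biallelic
  SNPs), effect-allele frequencies uniform on a configurable range (default
  0.05–0.5), dosages Binomial(2, EAF) (Hardy–Weinberg), strand-unambiguous
  allele pairs, completely-at-random missingness (default 2%).
* **Exposures.** Each latent exposure is `scaled GRS + confounder loading +
  correlated Gaussian residual`, with the genetic scaling solved so the
  population R² of the exposure on its own unweighted GRS equals the
  preset — 1.14%, 0.63% and 0.03% for neuroticism, education and physical
  activity. Exposure correlation (default 0.3 between each pair) is induced
  by shared Gaussian factors, *not* shared genetics, so instruments stay
  trait-specific by construction; an unmeasured standard-normal confounder
  loads 0.3 on every exposure and 0.3 on the outcome, producing an upward
  OLS bias of about +0.12 on the neuroticism–satisfaction slope, the same
  order as the published observational-versus-causal gap.
* **Measurement.** Latent traits are mapped monotonically to questionnaire
  observables: neuroticism to an integer 0–12 score by fixed quantile
  binning (`round(4.13 + 3.24 z)`, truncated — location and scale follow the
  published summaries of the EPQ-N short scale); education to a highest
  qualification category (population shares roughly matching a UK cohort)
  that the derivation module maps back to a leaving age of 15–21 years;
  physical activity to weekly days and minutes of walking, moderate and
  vigorous activity that recompose, through the IPAQ MET formula, to a
  log-normal MET-minutes target (median 1,200, log-SD 1, giving an SD of
  about 2,600 MET-minutes — close to the published figure).
* **Outcome.** The latent outcome is built from the *measured* standardised
  exposures at the configured causal effects (defaults −0.31, 0.02, 0.08
  outcome units per exposure SD), plus the confounder, optional per-allele
  direct effects of planted pleiotropic variants, and unit-variance noise.
  Defining effects on the measured scale makes `true_effects` exactly the
  estimand of the TSLS/MVMR stages, which see only measured z-scores. The
  default outcome scale is this continuous latent variable, so recovery
  experiments have a sharply defined target; `outcome_scale = "likert6"`
  discretises it to the 1–6 questionnaire scale (skewed towards
  satisfaction) for pipeline realism, and downstream models then treat the
  integer scale as continuous, as the emulated study does.
* **Cohort structure.** Age uniform on 37–73, 53% female, 22 assessment
  centres, Gaussian Townsend index, log-normal BMI, an employment indicator
  (default rate 73,296/315,536 — only employed participants have a
  job-satisfaction response) and six exclusion flags drawn at the published
  attrition fractions (consent withdrawal, sex mismatch, relatedness,
  non-British ethnicity, ICD-10 mental/neurological history, missing
  neuroticism).

One integer seed drives everything through deterministic per-component
sub-streams, so a fixed seed reproduces the cohort bit for bit.

What the generator does *not* emulate: linkage disequilibrium, imputation
uncertainty, family structure, genotyping batch effects, zero-inflation of
reported activity, or covariate effects on exposures (covariates are
exogenous controls here). Passing tests therefore demonstrate correctness
of the estimators and procedures under the assumed structure, not
robustness to these real-data features.

## Phenotype derivation choices

* The MET formula multiplies days/week by typical daily minutes and the
  IPAQ coefficients 3.3 / 4.0 / 8.0; "days with at least a 10-minute bout"
  is read as the questionnaire's definition of a countable day, following
  IPAQ short-form scoring.
* Duration outliers are those with |z| strictly above 3.29, z computed on
  the raw durations in a single pass; outlying values are set missing while
  the participant is retained for other analyses.
* The qualification-to-leaving-age mapping (none→15, CSE/O-level/GCSE→16,
  A-level→18, NVQ/HND→19, other professional→20, degree→21) is a documented
  stand-in — the emulated study's exact table is not public — and is fully
  overridable.
* MET and BMI are log transformed before use; MET as log(MET + 1) so zero
  activity is representable.
* z-scores are computed on the post-exclusion analysis sample with the
  n−1 SD; exclusion follows the published order with first-flag attribution,
  and the attrition cascade is logged.
* The quality filter keeps variants with call rate ≥ 90% (strictly-below
  removal), missing dosages are mean-imputed as twice the in-sample
  effect-allele frequency (a drop-per-sample mode is provided since scoring
  tools differ), and strand-ambiguous A/T–C/G variants are dropped in
  strict alignment mode.

## The validity screen and its null

Each panel variant is tested twice: trait ~ SNP + age + sex, and
job satisfaction ~ SNP + trait + age + sex + centre + TDI (a minimal
age/sex adjustment is available). A variant is retained only if it is
nominally associated with its trait (p < 0.05) and not with the outcome
(p ≥ 0.05); no multiplicity correction is applied by default, matching the
emulated procedure. The implementation partials the covariates out once per
panel (Frisch–Waugh), which is exactly equivalent to the per-variant least
squares fits and screens hundreds of variants in a few matrix operations;
equivalence with `lm()` is asserted in the tests.

One property deserves emphasis: the outcome test conditions on the measured
exposure, which is a *collider* between the variant and any unmeasured
confounder of exposure and outcome. With confounding present, valid
variants acquire a small spurious outcome association — at 50,000 samples
and per-variant first-stage t around 5, the false-exclusion rate rises from
the nominal 5% to roughly 17%. This is a property of the published
procedure, not of its implementation here. The suite therefore checks the
screen's error rates under its own null (no unmeasured confounding), where
a valid variant fails the outcome test at the nominal rate, and checks
separately that planted pleiotropic variants are caught with probability
near one. A companion test demonstrates the winner's-curse effect: screening
a genuinely weak panel concentrates in-sample instrument strength, so the
sensitivity GRS shows a higher first-stage F than the full score — the
direction reported for the physical-activity instrument in the emulated
study.

## Experiment design of the statistical acceptance checks

The recovery experiments state sample sizes as *analysed* samples: they
disable the exclusion flags and set full employment so that n means the
number of rows entering the fits, leaving all other defaults in place.
Problem sizes were fixed in advance as a balance of Monte-Carlo resolution
against runtime on a single CPU:

* TSLS recovery: 200 cohorts of n = 20,000 at the 1.14% preset, true effect
  −0.31, default confounding. Checks: mean estimate within 2 Monte-Carlo
  standard errors of −0.31, 95% CI coverage in [0.93, 0.97], OLS biased
  away by more than 3 Monte-Carlo SEs (and by more than 0.05 in absolute
  terms). Panels for the two non-focal traits are reduced to 8 variants —
  they do not enter the univariable fit.
* MVMR recovery: 200 cohorts, direct effects (−0.32, 0, 0), exposure
  correlation 0.3, default confounding, with every instrument in the
  identified regime (the physical-activity panel preset is raised to 0.5%
  for this experiment, conditional F ≈ 80; at the published 0.03% preset
  the conditional F is about 6, where the multi-stage estimator's O(1/F)
  finite-sample bias on correlated coefficients is the same size as the
  Monte-Carlo resolution and the package itself flags inference as
  unreliable). All three direct effects must fall within 2 Monte-Carlo SEs.
  Own- versus all-instrument agreement is checked as the exact algebraic
  statement — on data whose cross first-stage coefficients are exactly
  zero the two modes share identical fitted values and agree to machine
  precision. (A Monte-Carlo agreement check is deliberately not used: with
  hundreds of instruments the all-instrument mode carries a k/n
  overfit-instrument bias of order 0.007 at n = 20,000 that the
  own-instrument mode does not, a real difference between the estimators.)
* Power calibration: 1,000 cohorts of n = 2,000 at R² = 0.01, β = 0.2. The
  TSLS fit analyses the standardised latent exposure the generator retains
  for testing, on which the R² preset holds exactly; every questionnaire
  measurement map attenuates the realised first-stage NCP (the 0–12
  binning by ~6%, and even the near-affine log-MET route loses ~6% through
  one-sided trimming of the heavy-tailed durations), which would shift the
  premise of the comparison rather than test the power formula.
* Screening: 20 cohorts of n = 50,000 with 10 pleiotropic variants
  (per-allele direct effect 0.1) planted in a strongly-trait-associated
  136-variant panel (panel R² 15%, common variants with EAF 0.2–0.5, so
  *every* variant has per-variant power ≈ 1), no confounding (the screen's
  null, above). Checks: all 10 caught in every replicate; ≥ 90% of valid
  variants retained on average.

## Numerical notes and limitations

* All least-squares and projection steps use QR factorisations; rank
  deficiency, zero instrument partial variance, constant vectors and
  empty analysis frames raise informative errors rather than propagating
  NaNs. Degenerate screens (monomorphic variants) are excluded with a
  reason code instead of failing.
* Centre enters models as reference-coded indicators (first sorted level as
  reference). Robust (heteroskedasticity-consistent) standard errors are
  deliberately not the default — the emulated analysis used classical IV
  standard errors — and are out of scope.
* Just-identified TSLS has no finite-sample mean; recovery checks therefore
  run at first-stage F in the hundreds, where the normal approximation is
  accurate. At F near 10 the reported CIs remain honest in the suite's
  checks, but weak-instrument inference (Anderson–Rubin intervals etc.) is
  not implemented and F < 10 is flagged instead.
* The likert6 outcome rescales the latent effects by the discretisation
  map; causal effects are therefore calibrated on the latent scale only.
* Two-sample summary-statistic MR estimators, LD-aware scoring, weighted
  scores and binary-outcome power are out of scope.
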