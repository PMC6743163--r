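# metcal

Calibrating the MET intensities of a physical-activity questionnaire
against accelerometer energy expenditure.

## What this solves

Short self-administered questionnaires are the only practical way to
measure physical activity in cohorts of tens of thousands of working
women, but converting "hours per week of standing / walking / heavy work /
moderate exercise…" into energy expenditure requires a metabolic-equivalent
(MET) value per answer category, and assigned midpoint values are little
more than guesses. `metcal` estimates the eight reference METs
(MET₁…MET₈: sitting, standing, walking, heavy work, moderate, vigorous,
very vigorous, residual light activity) by Bayesian calibration against a
validation cohort wearing a waist accelerometer, then propagates both MET
sets through an age-stratified baseline cohort to compare total energy
expenditure (TEE) and moderate-to-vigorous activity (MVPA) patterns.

The core model: daily questionnaire TEE is

    TEE = BMR·(sleep/24) + TEF + Σᵢ weight·1.05·(PAᵢ/7)·METᵢ ,  TEF = TEE/10

with BMR from a (sex, age-band) basal-metabolic standard table and body
surface area BSA = weight^0.444 · height^0.663 · 88.83 (cm²). Calibration
assumes device TEE ~ Normal(questionnaire TEE, σ²) with gamma priors on
the METs (mean = the midrange values, shape 4) and a half-normal prior on
σ, sampled by adaptive random-walk Metropolis-within-Gibbs (1,000 burn-in,
10,000 kept draws). Agreement is judged by paired differences,
Bland–Altman limits of agreement and ICC(2,1); cohort contrasts use
one-way ANOVA + Tukey HSD (TEE) and the Jonckheere–Terpstra trend test +
pairwise Mann–Whitney with Bonferroni correction (MVPA).

Because neither study's raw data are public, the package ships seeded
synthetic-cohort generators that emulate the published marginal structure
of both samples; every analysis runs end to end on those.

## Worked example

The `analysis/` directory is the two-study workflow as numbered drivers;
each is a thin script over package functions:

```sh
Rscript analysis/01_simulate_validation.R   # validation cohort (n = 31)
Rscript analysis/02_calibrate_mets.R        # Bayesian MET calibration
Rscript analysis/03_agreement.R             # questionnaire-vs-device agreement
Rscript analysis/04_simulate_baseline.R     # baseline roster + exclusions
Rscript analysis/05_cohort_trends.R         # age-group TEE / MVPA contrasts
```

Step 2 prints the calibrated reference METs with 95% credible intervals
(here on the default-seed synthetic cohort, generated with true METs
1.2/1.6/1.8/4.5/2.4/4.4/9.4/1.1 and 150 kcal device noise):

```
calibrated on 31 records; acceptance rates 0.42-0.47
posterior reference METs (mean [95% CrI]):
  sitting         1.4  [1.04, 1.81]   ESS  680
  standing        1.3  [0.68, 1.81]   ESS  542
  walking         1.4  [0.80, 1.95]   ESS  344
  heavy_work      5.6  [2.74, 8.59]   ESS  692
  moderate        3.4  [1.01, 6.81]   ESS 1900
  vigorous        5.8  [1.62, 12.40]   ESS 1938
  very_vigorous   9.8  [2.63, 21.37]   ESS 2201
  light           1.1  [0.92, 1.29]   ESS  242
  residual sigma 150 kcal/day [115, 201]
```

Categories with substantial reported time (sitting, standing, walking,
light) are pinned tightly; rarely reported categories (moderate, vigorous,
very vigorous) stay close to their priors with wide intervals — at n = 31
that is the expected behaviour, not a failure. Step 3 then shows why the
calibrated values matter — the calibrated questionnaire agrees with the
device, the midpoint-valued one overshoots by ~24%:

```
== estimated METs ==
  mean difference: 1.3 +/- 134.9 kcal/day (0.1%)
  limits of agreement: [-263.2, 265.8] kcal/day
  ICC(2,1): 0.87 (95% CI 0.76-0.94)
== midrange METs ==
  mean difference: 468.6 +/- 182.9 kcal/day (23.9%)
  limits of agreement: [110.1, 827.2] kcal/day
  ICC(2,1): 0.38 (95% CI -0.06-0.75)
```

and step 5 reproduces the qualitative cohort contrast: MVPA declines with
age more steeply under the estimated METs (moderate activity, 2.4 METs,
drops out of MVPA) than under the midrange METs (3.0 METs, included):

```
== estimated METs ==
  overall TEE 1890 kcal/day (median 1878); MVPA 3.5 h/week
  JT trend on MVPA: z = -7.90, p = 2.74e-15
== midrange METs ==
  overall TEE 2297 kcal/day (median 2282); MVPA 3.9 h/week
  JT trend on MVPA: z = -6.76, p = 1.41e-11
```

All tables land under `results/`. The same functionality is available
programmatically via `run_study1()` / `run_study2()`; see the vignette
(`vignettes/met-calibration.Rmd`) for the model, priors, generator design
and limitations.

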