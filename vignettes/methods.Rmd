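---
title: "Population pharmacokinetics of TMP/sulfonamide combinations in pigs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of TMP/sulfonamide combinations in pigs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmpsulfa)
```

## The problem

Trimethoprim (TMP) is co-formulated with sulfonamides at a fixed 1:5 dose
ratio in essentially all veterinary products. That dose ratio was designed,
in human medicine, to hold the *free plasma concentration* ratio near 1:19
(sulfonamide:TMP), the historically optimal synergy point — which works in
humans because sulfamethoxazole and TMP happen to share a half-life. In
growing pigs three different sulfonamides are used — sulfadiazine (SDZ),
sulfamethoxazole (SMX) and sulfadimethoxine (SDMX) — with elimination
half-lives ranging from about 2 h to about 14 h, so the free ratio drifts
over time, differently for each combination. `tmpsulfa` implements the full
analysis chain needed to quantify that drift at the herd level: a
two-compartment population pharmacokinetic (popPK) model with
inter-occasion variability and a bodyweight covariate, SAEM estimation with
below-quantification-limit (BLQ) censoring, internal-validation diagnostics
(IWRES, PWRES, NPDE, prediction-corrected VPC), protein-binding correction,
and Monte-Carlo simulation of free sulfonamide:TMP ratio trajectories
against the 1:19 target and the relaxed 1:10–1:50 band.

## Structural model

Each analyte follows a mammillary two-compartment model with first-order
elimination, parameterized by clearance `CL` (L/h/kg), central volume `V1`
(L/kg), inter-compartment clearance `Q` and peripheral volume `V2`. All
parameters are bodyweight-normalized, so doses are mg/kg and concentrations
mg/L (= µg/mL); time is in hours. The micro-constants are
`k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, and the hybrid exponents
`alpha >= beta` are the roots of `s² − (k10+k12+k21)s + k10·k21 = 0`
(computed via the stable `beta = k10·k21/alpha` form). IV doses are
instantaneous boluses by default — the injection duration is not reported
for the study's "slow" injections — with an optional zero-order infusion
duration. Extravascular doses (oral gavage, IM) enter a depot with
first-order rate `ka` and bioavailable amount `F·dose`, giving the
three-exponential closed form; when `ka` collides with a disposition
exponent (relative distance below 1e-8) the analytic repeated-pole limit
with its `t·e^{−λt}` term is used rather than a numerical perturbation.
Multiple dosing is exact linear superposition of shifted single-dose
solutions. Secondary parameters are `T1/2β = ln 2 / beta` and
`AUC(0–∞) = F·dose/CL`. Closed forms are verified in the test suite against
an independent stiff-ODE integration (deSolve, `rtol = 1e-12`) to a
relative 1e-8 over 1000 random parameter sets, and against the AUC
identities to 1e-4.

## Population model

Individual parameters are log-normal (logit-normal for `F`) around the
typical value, with a bodyweight power covariate normalized at the study
median of 31.1 kg:

log H_ik = log H_pop + β_BW · log(BW_ik / 31.1) + η_Hi + γ_Hik

`η` is inter-individual variability (IIV, one draw per pig) and `γ`
inter-occasion variability (IOV, one draw per pig-occasion). Following the
fitted pig models, IOV is carried by `CL`, `V1` and `V2` (with no extra
per-pig term — when only IOV is modeled, the per-pig level is implicitly
absorbed), IIV by `ka`; `Q` and `F` carry no random effect, nor does `ka`
for SMX, whose data could not support one. Bodyweight exponents exist for
`CL` and `V1` of SDZ (0.51, 1.1) and TMP (0.78, 1.33). `pig_population_models()`
returns the four fitted models (also shipped as a parameter-table CSV,
`pig_parameter_file()`); `typical_params()`, `draw_individual()` and the
vectorized `sample_parameters()` map them to concrete pigs.

Random-effect correlations are supported through a correlation matrix over
the occasion-level effects, but the published per-analyte correlation
values live in supplementary material that is not distributed with the
package, so the default is the identity — the consequences are discussed
under *Limitations*.

Worked covariate examples, reproduced by `scripts/acceptance.R`: a 41.1 kg
pig has typical CL 0.14 (SDZ) and 0.60 (TMP) L/h/kg, and typical V1 0.41
(SDZ) and 1.33 (TMP) L/kg. Typical terminal half-lives from the median
parameters are 3.7 h (SDZ), 2.2 h (SMX), 2.8 h (TMP) and 13.7 h (SDMX, in
the reported individual range 10.9–20.2 h).

## Protein binding

Only unbound drug is microbiologically active. Binding is assumed linear
over the observed range, so free concentration = total × mean `fu` with no
per-pig variability. The measured mean bound percentages are 29.2 % (SDZ),
57.3 % (SMX), 94.1 % (SDMX) and 51.2 % (TMP); the working unbound
fractions applied in the simulations are 0.708, 0.427, 0.059 and 0.489.
For TMP the study's working value (0.489) differs in the third decimal
from `1 − 51.2/100 = 0.488`; `binding_table()` stores the working value
and `fu_from_pb()` computes the arithmetic one, so either convention is a
one-liner.

## Synthetic studies

`study_design()`/`generate_study()` emulate the three cross-over trials:
each pig receives its combination once IV and once by oral gavage
(alternating order; 10, 10 and 14 pigs), at the licensed doses
(SDZ 12.5 + TMP 2.5 IV, 25 + 5 oral; SMX 30 + 6 both routes;
SDMX 18.6 + 4 IV, 37.36 + 8 oral, all mg/kg), sampled at
0.5–56 h (plus 5 and 15 min after IV; out to 96 h for SDMX). Bodyweights
are uniform over each trial's printed range and re-drawn at each occasion,
since pigs were weighed before each period. Observations are
`true_conc × exp(ε)`, `ε ~ N(0, a²)` — the constant residual error on the
log scale, with the fitted `a` of 0.32/0.22/0.18/0.40 for
SDZ/SDMX/SMX/TMP. Censoring follows the assay limits: at or above the LOQ
(0.1 µg/mL for SDZ and SDMX, 0.02 for SMX, 0.01 for TMP) a value is
observed; between LOD and LOQ it is interval-censored; below LOD
left-censored. The LOD is not reported and defaults to LOQ/2, a common
bioanalytical convention, and is configurable. `inject_outliers()`
flags and distorts a chosen fraction of rows so that exclusion workflows
(the trial removed 155 of 1858 points) are testable. Repeated-dosing
presets (`preset_design()`) cover oral q12h and IM q24h five-day regimens.

What the generator does *not* emulate: assay drift (the SMX >12 h failure
is available only as the `filter_smx_late()` truncation), drinking-water
dosing variability, growth within a period, or correlated random effects
unless a correlation matrix is supplied. Passing tests on synthetic data
therefore demonstrate internal consistency of estimator and generator
under the stated model, not robustness to the real data's quirks.

## Estimation

`fit_population()` maximizes the marginal likelihood by SAEM. Latent
variables are the link-scale individual parameters of every
random-effect-carrying parameter per pig-occasion. The E-step is
Metropolis-within-Gibbs with three ingredients:

* component-wise random-walk sweeps with acceptance-rate adaptation
  (target 0.4) and a prior-independence refresh kernel;
* a **Laplace independence kernel**: every `laplace_every` iterations the
  occasion's posterior is approximated by a Gaussian at its mode
  (BFGS + numeric Hessian) and joint proposals are drawn from it with the
  exact Metropolis-Hastings correction. This is what keeps mixing healthy
  on the narrow, strongly correlated posterior ridges that arise when the
  residual error is small — in a deterministic-data check, random walks
  alone stalled several percent away from the optimum;
* censored observations are imputed from their truncated normal
  conditionals, so the complete-data model stays Gaussian.

M-steps are closed-form regressions of the simulated latents on the
intercept-plus-`log(BW/31.1)` design (giving `H_pop`, `β_BW`, and the
variance), with Robbins-Monro averaging (step 1 during exploration, `1/k`
during smoothing) and a simulated-annealing floor that limits per-iteration
variance shrinkage to 5 %. Parameters without random effects (`Q`, `F`)
are genuine fixed effects: they are updated by damped diagonal-Newton
steps on the complete-data residual sum of squares, with a full BFGS
refresh every `fix_bfgs_every` iterations. (An earlier design gave them
occasion-level latents with a small auxiliary prior; that freezes on the
logit scale — the prior pins the latent to the current estimate and the
update loop becomes self-referential — and was discarded.)

Defaults are 300 exploration + 100 smoothing iterations, 2 random-walk
sweeps; none of these appear in the source study, so they are exposed in
`saem_control()` and seeded. Convergence is monitored as the relative
parameter drift over the second half of the smoothing phase (warning above
10 %). With one extravascular occasion per pig (the cross-over design),
`ka`'s IIV is operationally an occasion-level latent and is implemented as
such.

The marginal log-likelihood for model comparison comes from a per-pig
Laplace approximation at the joint latent mode (which also yields the
empirical Bayes estimates). `bicc()` applies a hybrid small-sample
penalty: parameters tied to the random-effect structure count against
`log(N_subjects)`, purely fixed parameters and the residual SD against
`log(n_observations)`; the exact variant used by the original software is
not published, so this definition is documented and tested against its own
formula. `bootstrap_se()` case-resamples pigs (default 100 replicates, as
in the study), refitting every replicate from a single fit seed so that
the replicate spread reflects the data, not the sampler.

Parameter-recovery performance under the study conditions (n = 20 pigs,
two occasions, SDZ truth): median absolute errors over five seeds are
about 7 % (CL), 12 % (V1), 18 % (Q), 9 % (V2) and 4 % (ka), with the
one-compartment/two-compartment BICc comparison picking the generating
model in 5/5 seeds. These runs use 250 + 250 iterations — at shorter
smoothing the estimator's own Monte-Carlo noise, not bias, dominated the
error in `Q`.

## Diagnostics

All residuals work on the log-concentration scale, matching the
log-additive error model. `iwres()` standardizes observed minus individual
(EBE) predictions by `a`. `pwres()` and `npde()` simulate `K` replicate
datasets at the observed design: PWRES decorrelates each pig's
observations with the Cholesky factor of the empirical between-replicate
covariance; NPDE additionally decorrelates every simulated replicate,
takes exceedance ranks, applies the `1/(2K)` continuity correction at the
extremes and maps through the inverse normal CDF, reporting a
Kolmogorov–Smirnov test against N(0,1). Censored rows are excluded from
residual computation (their count is reported); a singular simulation
covariance is ridge-regularized with a warning.

`pcvpc()` is a prediction-corrected VPC with 500 simulations by default,
stratified by route: observations and simulations are shifted, on the log
scale, by the difference between the bin-median typical prediction and the
row's own typical prediction; empirical 10/50/90th percentiles per
quantile-based time bin (8 bins by default — the binning is not specified
in the source study) are compared to 5–95 % envelopes of the replicate
percentiles; singleton bins merge into their neighbor. Under the true
model the NPDE pass the KS test at α = 0.01 in 5/5 calibration seeds and
over 80 % of pcVPC percentile points fall inside their envelopes; doubling
CL breaks both (KS p < 1e-9, coverage ≈ 0.1). A twofold CL error shifts
the mean NPDE by ≈ +0.4 rather than the ±0.5 one might expect, because the
late, most discrepant samples are BLQ-censored and excluded; detection is
therefore asserted through the KS statistic.

## Herd ratio simulations

`simulate_cohort()` draws `n` virtual pigs (default bodyweight range equal
to the relevant trial's range) and computes total concentration curves for
both analytes of a combination on a 0–24 h grid with 0.1 h steps, at the
maximum labeled oral doses (25 mg/kg SDZ or SMX + 5 mg/kg TMP;
37.36 mg/kg SDMX + 8 mg/kg TMP). Draws are pig-major, so enlarging a
cohort under the same seed leaves the first pigs unchanged. The free ratio
is `R(t) = fu_S·C_S(t) / (fu_TMP·C_TMP(t))`, in "1:R" orientation (1:19
⇒ R = 19). `band_metrics()` reports every candidate occupancy summary for
the 1:10–1:50 band: the proportion of pigs ever in band (the documented
headline), always in band, per-pig time fraction, and per-pig in-band
duration with its median (a pig's duration is the grid length covered,
`(points − 1) × Δt`). Grid-refinement and seed-stability checks hold these
metrics to within 0.5 and 1 percentage points respectively.
`accumulation_sim()` runs multi-day regimens and reports per-day band
metrics and pre-dose troughs; with SDMX q24h the day-5 trough exceeds the
day-1 trough by the closed-form accumulation factor
`1/(1 − e^{−beta·24}) ≈ 1.42`.

With identity correlations the three combinations order as
SMX < SDZ < SDMX in both time-in-band and ever-in-band tendency, SMX's
typical ratio leaves the band downward within a few hours, SDZ's is by far
the most nearly constant, and SDMX's rises through the band as TMP clears
faster — all consistent with the source study's qualitative account.

## Numerical choices and degenerate inputs

* `q = 0`/`v2 = 0` collapses to the one-compartment model everywhere
  (`beta` then means `k10`); the two-compartment IV solution converges to
  the one-compartment limit as `q → 0` (tested).
* Non-positive predictions at an observation time contribute `-Inf`
  likelihood rather than an error; interval probabilities are floored at
  1e-300 before logging.
* Truncated-normal sampling uses inverse-CDF with clamping at 1e-12 of
  probability mass.
* `0/0` ratio points (pre-dose, oral) are `NA` and masked from band
  metrics.
* Time-unit invariance of the likelihood under h→min rescaling of times
  and rate constants is tested.

## Limitations

The dominant one: without the published random-effect correlation matrix
the simulated herd variability is too free, which inflates the spread of
ratio trajectories — nearly every simulated pig touches the 1:10–1:50 band
at least once, so the *ever-in-band* proportions saturate and the study's
printed 8.8 % / 46.8 % / 76.5 % cannot be reproduced, only the ordering
and profiles. Supplying `corr` on the population models restores the full
machinery. Parameter-uncertainty propagation (refitting bootstrap
posteriors into the simulation layer) is available only insofar as
bootstrap replicate tables can be fed back as population models; the herd
defaults use point estimates. The estimator assumes at most one
variability level per parameter (IIV or IOV), which is exactly the
published placement but not fully general. The real trials' raw data are
not bundled; every dataset here is synthetic, clearly labeled as such, and
the problem sizes used in the test suite (6–20 pigs, 150–500 SAEM
iterations, cohorts of 10,000) are the package's own choices for its
calibration studies.
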