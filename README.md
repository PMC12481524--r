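# tmpsulfa

Population pharmacokinetics of trimethoprim (TMP) combined with
sulfadiazine (SDZ), sulfamethoxazole (SMX) or sulfadimethoxine (SDMX) in
growing pigs — for veterinary pharmacologists and dose-regimen modelers
who want to ask: *at the labeled 1:5 dose ratio, how often does the free
plasma concentration ratio of sulfonamide to TMP actually sit near the
1:19 synergy target, or at least inside the relaxed 1:10–1:50 band?*

## What is inside

The core is a nonlinear mixed-effects (popPK) model per analyte: a
two-compartment disposition with first-order absorption,

- micro-constants `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, hybrid
  exponents `α, β` solving `s² − (k10+k12+k21)s + k10·k21 = 0`, and
  `T½β = ln 2 / β`, `AUC∞ = F·D/CL`;
- individual parameters
  `log H_ik = log H_pop + β_BW·log(BW/31.1) + η_i + γ_ik`
  (log-normal; logit-normal bioavailability), with inter-occasion
  variability on CL/V1/V2, inter-individual variability on ka, and a
  bodyweight power covariate on CL and V1 of SDZ and TMP;
- log-scale constant residual error with interval censoring between LOD
  and LOQ and left censoring below LOD.

Around it: SAEM estimation with censored-data imputation and a
Laplace-based marginal likelihood/BICc, case-resampling bootstrap SEs,
simulation diagnostics (IWRES, PWRES, NPDE, prediction-corrected VPC),
protein-binding correction to free concentrations (`fu` = 0.708, 0.427,
0.059, 0.489 for SDZ/SMX/SDMX/TMP), a synthetic cross-over study
generator reproducing the trial design, and Monte-Carlo herd simulation
of free S:TMP ratio trajectories with band-occupancy metrics and
multi-day accumulation.

## Worked example

```r
library(tmpsulfa)
pops <- pig_population_models()          # fitted models for SDZ/SDMX/SMX/TMP

# typical SDZ kinetics for a 41.1 kg pig (bodyweight covariate applied)
p <- typical_params(pops$SDZ, 41.1)
p
#> <structural_params> 2-compartment
#>   CL = 0.138335 L/h/kg, V1 = 0.407672 L/kg, Q = 0.32 L/h/kg, V2 = 0.29 L/kg
#>   ka: oral = 0.5 /h, im = 1.3 /h
#>   F:  oral = 0.93, im = 0.99
terminal_half_life(p)      # 3.8 h
auc_inf(p, 25, "oral")     # 168 h*ug/mL

# herd simulation: free SDZ:TMP ratio at the labeled oral doses
h <- herd_ratio_simulation("TMP/SDZ", n = 10000, seed = 1)
h$band$fraction_ever_in_band          # 0.944
h$band$median_duration_in_band        # 7.0 h
mean(h$band$time_fraction_in_band)    # 0.404
```

The first block says a heavier-than-reference pig clears SDZ at
0.14 L/h/kg with a 3.8 h terminal half-life. The second simulates 10,000
pigs at 25 mg/kg SDZ + 5 mg/kg TMP orally: 94 % touch the 1:10–1:50 free
ratio band at some point in 24 h, the median pig spends 7 h inside it,
and the herd spends about 40 % of pig-time in band. (Without the
unpublished random-effect correlations the absolute proportions are wider
than the source study's; the combination ordering SMX < SDZ < SDMX and the
profile shapes are the robust outputs — see the methods vignette.)

Fitting and diagnostics on synthetic data:

```r
d   <- generate_study(study_design("TMP/SDZ", n_pigs = 20), pops, seed = 1)
fit <- fit_population(d, "SDZ", estimate_beta_bw = c("cl", "v1"), seed = 2)
coef(fit); fit$bicc
nn  <- npde(d, "SDZ", pops$SDZ, K = 500, seed = 3); attr(nn, "ks")
vpc <- pcvpc(d, "SDZ", pops$SDZ, K = 500, seed = 4)
```

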