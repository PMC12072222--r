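# coprokin

Coproporphyrin-I (CP-I) is a metabolically stable byproduct of heme
synthesis and the consensus Tier-1 endogenous biomarker of the hepatic
uptake transporters OATP1B1 and OATP1B3: drugs that inhibit OATP1B raise
CP-I plasma levels, so monitoring CP-I in early clinical trials can flag
transporter-mediated drug–drug interaction (DDI) risk without dosing a
probe drug. `coprokin` is an R package for scientists doing that kind of
model-informed DDI assessment. It implements a lumped physiologically based
pharmacokinetic (PBPK) model of CP-I and generic OATP1B victim drugs, and
the analyses built on top of it:

* **baseline simulation** across ethnicity, *SLCO1B1* c.521T>C genotype and
  sex covariates (18 scenarios), deterministic or with between-subject
  variability;
* **DDI prediction** for weak-to-strong OATP1B inhibitors under competitive
  inhibition, reporting CP-I CmaxR and AUCR;
* **inverse estimation of in vivo OATP1B Ki** from observed interaction
  ratios or concentration profiles, with sensitivity analysis to the
  assumed renal elimination fraction;
* **phase-I trial-design simulation** comparing CmaxR and AUCR as
  monitoring metrics for virtual inhibitors of different potency and
  half-life;
* **model-evaluation statistics** (1.5-fold/2-fold criteria, the Guest
  acceptance band, geometric mean fold error) and **synthetic-data
  generators** so the whole pipeline is testable without clinical data.

## The model

CP-I is synthesized in blood at a zero-order, weight-proportional rate
k_syn (mg/day/kg) and eliminated renally (CL_R, plasma-referenced) and
hepatically. The liver is permeability-limited: three mass-balanced
compartments (central plasma, liver extracellular, liver intracellular)
with

* sinusoidal uptake by OATP1B1 and OATP1B3 (per-cell intrinsic clearances
  CL_int scaled to whole liver by hepatocellularity × liver mass), plus a
  small passive term CL_pd acting in both directions,
* canalicular (biliary) secretion by MRP2,
* competitive inhibition of each uptake transporter by the unbound
  liver-inlet perpetrator concentration: CL_int,T / (1 + I_u/K_i,T).

At baseline the steady state is solved exactly from the linear system; at
steady state the hepatic side reduces to the well-stirred form
CL_H,b = Q_H·fu_B·CL_int,net / (Q_H + fu_B·CL_int,net) with
CL_int,net = CL_uptake,total · CL_bile/(CL_bile + CL_pd). A single hepatic
activity scaler γ reconciles in vitro per-cell clearances with the clinical
baseline; it is calibrated by root-finding against either a target renal
fraction f_e or a target baseline concentration (see
`calibrate_hepatic_scaler()`). With the default calibration (f_e = 10%),
the fractions of CP-I elimination are ≈69% OATP1B1, ≈20% OATP1B3, 10%
renal, <1% passive.

## Worked example

```r
library(coprokin)

phys <- physiology_ref()                    # 70-kg reference subject
cpi  <- calibrate_victim(cpi_victim(), phys, fe = 0.10)

solve_baseline(cpi, phys)
#> # A tibble: 1 × 9
#>   css_nM cl_total_plasma cl_hepatic_plasma cl_renal_plasma    fe ft_oatp1b1
#>    <dbl>           <dbl>             <dbl>           <dbl> <dbl>      <dbl>
#> 1  0.697              23              20.7             2.3   0.1      0.693
#>   ft_oatp1b3 ft_passive ft_renal
#>        <dbl>      <dbl>    <dbl>
#> 1      0.203    0.00497      0.1
```

The predicted baseline (0.697 nM) sits within 2% of the 0.685 nM
meta-analytic mean for White male wild-type subjects, with a total plasma
clearance of 23 L/h split 90:10 between the hepatic and renal routes.

A single 600 mg dose of an illustrative rifampicin-like inhibitor
(in vitro Ki 0.16/0.088 µM for OATP1B1/1B3):

```r
out <- simulate_ddi(cpi, example_inhibitor("rifampicin-like"),
                    dosing_regimen(600, 24, 1), phys, window = c(0, 24))
out
#> <ddi_outcome> CP-I + rifampicin-like (illustrative, non-validated) 600 mg
#>   window 0-24 h:  CmaxR 4.291  AUCR 2.042  Tmax 2.30 h
```

CP-I peaks at 4.3× its baseline 2.3 h after the dose while the 24-h AUC
doubles — the peak ratio is the more sensitive interaction metric. Given an
*observed* AUCR (here 4.6, the strong end of reported CP-I interactions),
the in vivo Ki implied by the biomarker model is recovered by inverting the
forward simulation:

```r
estimate_ki_from_ratio(4.6, "AUCR", cpi, example_inhibitor("rifampicin-like"),
                       dosing_regimen(600, 24, 1), phys)
#> <ki_estimate>
#>   OATP1B1 Ki 0.01275 uM (aucr_match, fe assumed model default)
#>   map: OATP1B1 0.01275, OATP1B3 0.007015
#>   residual 7.03e-14 after 13 evaluations
```

an order of magnitude below the in vitro value, the usual direction of the
in vitro/in vivo disconnect for OATP1B inhibition. `fe_sensitivity()`
quantifies how strongly such estimates depend on the assumed renal
fraction, and `run_trial_design_grid()` reproduces the monitoring-metric
recommendations (CmaxR for strong/moderate short-half-life inhibitors,
CmaxR or AUCR otherwise; single-dose assessment suffices only for short
half-lives).

See the methods vignette (`vignettes/cpi-pbpk-model.Rmd`) for the model
equations, parameter provenance, calibration and all numerical choices.

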