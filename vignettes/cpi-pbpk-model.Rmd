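---
title: "The CP-I PBPK model: structure, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CP-I PBPK model: structure, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coprokin)
```

Coproporphyrin-I (CP-I) is an endogenous byproduct of heme synthesis whose
plasma level is controlled by hepatic OATP1B1/OATP1B3 uptake; it rises when
those transporters are inhibited, which makes it a practical biomarker for
OATP1B-mediated drug–drug interaction (DDI) risk. This vignette documents
the model `coprokin` implements, where each parameter comes from, what was
calibrated, and the design decisions taken where the underlying science
leaves the implementation genuinely open.

## Model structure

The victim (CP-I, or a dosed OATP1B substrate) moves through three
mass-balanced compartments — central plasma, liver extracellular
(sinusoidal + interstitial), and liver intracellular — with amounts in
nmol:

* **Central**: zero-order synthesis in blood (`k_syn` × body weight,
  endogenous victims) or first-order oral absorption (dosed victims);
  renal elimination `CL_R · C_p`; hepatic blood-flow exchange with the
  liver extracellular space.
* **Liver extracellular**: flow in at the arterial/portal blood
  concentration, out at the local concentration; unbound active uptake by
  OATP1B1 and OATP1B3 plus passive diffusion into the hepatocyte; passive
  backflux out of it.
* **Liver intracellular**: uptake in; passive backflux and MRP2-mediated
  biliary secretion out. Biliary output leaves the system (no
  enterohepatic recirculation).

Competitive inhibition divides each active uptake clearance by
`1 + I_u/K_i,T`, where `I_u` is the unbound perpetrator concentration at
the liver inlet. The system is linear for any fixed inhibitor exposure, so
the baseline steady state is obtained by solving the 3×3 linear system
exactly rather than by long integration; the ODE route (`simulate_victim()`)
is retained for time-varying inhibition and is tested to agree with the
linear solve to 0.01%.

### Blood/plasma and binding bookkeeping

Flow terms act on blood concentrations (`C_b = C_p · B/P`); `CL_R` is a
plasma-referenced clearance, as renal clearances are reported clinically.
The unbound fraction driving sinusoidal transport is the blood-referenced
`fu_B = fu_plasma/(B/P)`. Intracellular binding cancels out of the net
hepatic clearance because both intracellular exit routes (biliary, passive
backflux) act on the same unbound pool, so it is set to 1: only the ratio
`CL_bile/(CL_bile + CL_pd)` — the probability that a molecule taken up is
secreted rather than escaping back — matters, and that is binding-free.

### Parameters

CP-I compound values (`cpi_victim()`) are literature consensus inputs: MW
654.71 g/mol, LogP 2.53, ampholyte pKa 3.56/5.18, B/P 0.628, fu_plasma
0.069, CL_R 2.3 L/h (weighted mean of clinical measurements, range 1.1–3.0
L/h), per-cell intrinsic clearances (µL/min/10⁶ cells) OATP1B1 106,
OATP1B3 31, MRP2 0.612, passive 0.76 (all RAF = 1), and synthesis rates
(mg/day/kg) of 0.0036/0.0032 (male/female, White and Asian-Indian) and
0.0024/0.0021 (Japanese). LogP and pKa are carried for provenance but
unused: the lumped model does not predict tissue partitioning.

Reference physiology (`physiology_ref()`): liver 1650 g at 99×10⁶ cells/g,
hepatic blood flow 87 L/h (portal 66 L/h), haematocrit 0.45, volumes
5 L central plasma / 0.283 L liver extracellular / 1.04 L liver
intracellular. The central volume is a lumped stand-in for whole-body
distribution; CP-I baseline and all steady-state ratios are insensitive to
it (it shifts transient kinetics only), and every volume is configurable.

### Scaling and allometry

Per-cell clearances scale to whole liver as
`CL_int · hepatocellularity · liver mass · RAF · γ` with µL/min → L/h
conversion (`scale_intrinsic_clearance()`). Whole-liver intrinsic
clearances and blood flows scale with `(BW/70)^0.75`, volumes with
`(BW/70)`. `CL_R` is deliberately **not** allometrically scaled: it is an
observed clinical clearance adopted as-is, whereas the hepatic side is
built up from in vitro data and needs size scaling. (Scaling `CL_R` too
would move the female:male baseline ratio from 0.845 to 0.855; the fixed
convention is also what keeps the renal pathway anchored to its measured
value.)

## Calibration: the hepatic activity scaler γ

In vitro per-cell clearances never extrapolate exactly to the in vivo
organ; some reconciliation against clinical observation is always present
in transporter PBPK models, usually hidden in platform scaling factors.
`coprokin` makes it explicit: a single scaler γ multiplies all per-cell
hepatic clearances (uptake, passive, efflux — uniformly, so the
bile-commitment ratio is untouched) and is fitted by monotone bracketing
root-finding (`uniroot` on log γ, bracket 10⁻⁸–10⁸, target met to 0.1%)
against either

* a renal elimination fraction (`fe = 0.10`, the package default, from the
  observed `CL_R` of 2.3 L/h against a total clearance of 23 L/h), or
* a baseline concentration (e.g. the 0.685 nM meta-analytic mean).

Both targets give γ ≈ 0.80–0.83 at the White-male reference, i.e. the in
vitro clearances need a ~20% trim. Calibration has a closed-form
well-stirred oracle — invert `CL_H,b = Q·x/(Q + x)` for
`x = fu_B·CL_int,net·γ` — which the root-find is tested against. Targets
outside the attainable envelope (e.g. fe below the renal-only floor set by
the liver blood-flow limit) raise a calibration error with the bracket
diagnostics.

## Covariates

`apply_covariates()` starts from the calibrated White-male-521TT reference
and adjusts:

* **sex/ethnicity** on synthesis (`k_syn` table above; the female rate is
  88% of the male rate, tracking hemoglobin differences),
* **ethnicity** on OATP1B1 abundance (Japanese 58% of White; Asian-Indian
  kept at the White level because the reduction is reported for Japanese
  only — configurable),
* **genotype** on OATP1B1 activity, and
* **demographics** (White 70/60 kg M/F; Japanese and Asian-Indian
  65/52 kg).

*SLCO1B1* c.521T>C activity multipliers are not published as transportable
numbers, so they are a design choice here: TT 1.0, TC 0.72, CC 0.441. CC
was solved so that the White mixed-sex CC:TT baseline ratio equals the
clinically reported 1.4; TC is the gene-dose midpoint. The naive
gene-dose guess (CC ≈ 0.6) looks natural but ignores hepatic flow
limitation: at ~38% hepatic extraction a 40% cut in uptake activity moves
total clearance much less than proportionally, and yields a ratio of only
1.24. Solving through the flow-limited model is the consistent choice; the
multipliers are arguments of `apply_covariates()` for users who prefer
other conventions.

Population simulation (`sample_population()`) draws median-preserving
log-normal factors per subject — CV 0.35 on intrinsic clearances (one
common factor), 0.25 on synthesis, 0.30 on renal clearance, 0.15 on body
weight — standard magnitudes for hepatic transporter kinetics; the
representative subject is the population median by construction.

### Pathway fractions

`compute_ft()` reports the conventional intrinsic-clearance split:
`ft_T = (1 − fe)·CL_int,T/(ΣCL_int,uptake + CL_pd)`, giving 69%/20%
(OATP1B1/OATP1B3) at fe = 10% and <1% passive. Published fT values for
CP-I (66%/24%) imply a slightly different effective isoform ratio than the
in vitro CL_int ratio, presumably via platform abundance scalars; the
per-transporter RAF slots allow that convention to be configured, and the
CL_int-ratio values are reported by default.

## Perpetrator model and the inhibition driver

Inhibitors use linear first-order-absorption one- or two-compartment PK,
solved in closed form by eigen-decomposition and dose superposition (exact
between dose times — this also matters numerically, see below). Doses
enter the gut in full; `f_abs` (Fa·Fg) multiplies the absorption flux, so
`cl_over_f`/`v_central` act together with `f_abs` as the apparent oral
disposition, and no hepatic first-pass extraction of the inhibitor is
modeled.

The inhibition driver is the **dynamic unbound liver-inlet concentration**
`I_u = fu·(C_sys + ka·f_abs·A_gut/Q_portal,plasma)` — OATP1B uptake faces
portal blood, and during absorption the inlet can far exceed systemic
exposure. `simulate_ddi(driver = "systemic")` switches to systemic unbound
for sensitivity checks (it always predicts weaker interactions). For
probenecid-class inhibitors, in vitro IC50 values are used directly as Ki,
valid when the probe concentration is well below Km. The shipped
`example_inhibitor()` parameter sets carry literature Ki values but
generic, *non-validated* disposition parameters; quantitative reproduction
of specific trials requires user-supplied PK.

## The DDI engine

Control and treatment arms start from the identical initial state: the
analytic baseline steady state for endogenous victims (the clinical
"baseline day"), an empty system for dosed victims (which receive the same
victim regimen in both arms). Metrics (grid Cmax, trapezoid AUC) are
computed over an explicit window — the dosing day for single-dose designs,
the certified steady-state day for multiple-dose designs. The window is a
required, visible argument because reported clinical windows vary by
study.

A static extended-clearance oracle
(`static_aucr()` = `1/(Σft_T/(1+I/K_i) + 1−Σft)`) accompanies the dynamic
engine. The two agree (within 2%) only far from the hepatic flow limit;
for the CP-I parameter set itself (extraction ≈ 0.38) the static formula
overestimates intermediate inhibition and acts as an upper bound, which
the test suite asserts together with the saturation ceiling
`AUCR → 1/(fe + ft_passive)` as `I_u → ∞`.

## In vivo Ki estimation and the renal-fraction sensitivity

`estimate_ki_from_ratio()` inverts the forward simulation: bisection on
log Ki over 10⁻⁶–10⁴ µM until the simulated AUCR (or CmaxR) matches the
observation to 10⁻⁴ relative. A single scale factor moves both OATP1B Ki
values, preserving the in vitro OATP1B1:OATP1B3 ratio — one observed
ratio cannot identify two constants, so the one-dimensional search is the
identifiable choice. AUCR matching is the default objective; which metric
(or full-profile fit) underlies published in vivo Ki estimates is rarely
stated, so the objective is explicit in the result object.
Observations above the attainable ceiling raise an infeasibility error
naming the ceiling. `estimate_ki_from_profile()` adds a log-scale
least-squares fit to concentration profiles (for sparse/noisy synthetic
studies) with a curvature-based standard error and a flat-objective
(non-identifiability) flag — an inhibitor dose of zero is the canonical
trigger.

`repartition_clearance()` changes the assumed renal fraction while holding
total clearance — hence the baseline — fixed, recalibrating γ. Because the
renal route is not inhibitable, the assumed fe drives the estimated Ki
hard for strong inhibitors: the closed-form static solve gives a 3.4-fold
Ki drop between fe = 0 and fe = 0.15 at an observed AUCR of 4.6, and the
dynamic estimator (time-varying exposure) gives a substantially larger
fold, consistent with the several-fold sensitivities reported for strong
OATP1B inhibitors. `fe_sensitivity()` tabulates Ki and the downstream
consequence — the predicted AUCR of a statin-like victim
(`statin_like_victim()`, a synthetic generic substrate with OATP1B
fraction ≈ 0.7 and fe = 0.1, not a model of any marketed statin).

## Trial-design simulation

`virtual_inhibitor()` spans a potency × half-life grid: one-compartment
oral inhibitors (fu 0.1, ka 1 h⁻¹, V 115 L; CL 20 or 2.66 L/h for ~4 h and
~30 h half-lives), dosed once daily for ≥7 half-lives plus margin, with
the dose solved so the steady-state maximal unbound inlet concentration
over Ki hits 0.5 (weak), 3 (moderate) or 20 (strong). Exposure linearity
makes that solve a single probe simulation. `simulate_scenario()` reports
CmaxR/AUCR(0–24 h) on the steady-state day and refuses to report if the
day-over-day treatment AUC still changes by >0.5%.

Because these inhibitor parameters are package choices (the corresponding
published values are not available in transportable form), the trial-design
conclusions are asserted as orderings rather than percentages: CmaxR ≥
AUCR always; the CmaxR–AUCR gap is larger for short than long half-life at
matched potency; sparse-sampling error (`sparse_sampling_cmaxr()`,
convention: % reduction of the peak ratio over the control floor,
`100·(Cmax − C(t))/(Cmax − C_control)`) is zero at Tmax and grows
monotonically with distance from it. `recommend_metric()` encodes the
resulting design rules (CmaxR for strong/moderate-short, either metric for
weak-short and strong-long; multiple dosing needed only for long
half-life).

## Synthetic data

The generators stand in for clinical panels: `generate_baseline_dataset()`
(per-subject baselines, log-normal between-subject × residual structure,
the standard model for concentration data reported as means ± SD) and
`generate_ddi_dataset()` (paired control/treatment profiles simulated at a
known true Ki with multiplicative residual error, truth record attached).
Every generator is a pure function of (configuration, seed). They emulate
the *statistical structure* the estimators assume — they do not emulate
assay bias, quantification limits, dropout, diurnal rhythm, or model
misspecification, so passing recovery tests demonstrates estimator
correctness under the model, not robustness on real data.

## Numerical choices

* Victim ODE: `deSolve::lsoda`, rtol 10⁻⁸, atol 10⁻¹⁰ nmol; output grid
  ≤0.1 h; cumulative renal/biliary elimination carried as auxiliary states
  so mass balance is auditable (closes to 0.1% over transients).
* The inhibitor forcing passed to the stiff integrator is the *analytic*
  exponential solution, smooth between dose times. (An interpolated grid
  forcing introduces derivative kinks every grid step and makes lsoda
  re-step constantly — ~40× slower for identical results.)
* Steady states by exact linear solve; `solve()` on the 3×3 system.
* Root-finds on log scales with fixed generous brackets; Cmax ties break
  to the earliest grid time; AUC by trapezoid on the simulation grid.
* Degenerate inputs error early with typed conditions
  (`coprokin_invalid_parameter`, `coprokin_degenerate_model`,
  `coprokin_calibration_failure`, `coprokin_infeasible_observation`,
  `coprokin_ambiguous_victim`).

The test suite sizes were chosen to characterize the estimators well while
staying desk-scale: 18 deterministic covariate scenarios; 1000-subject
population draws for distributional checks; a 100-seed × 12-sample
recovery study at 20% residual CV for the profile estimator (median
recovered Ki within 25% of truth); long-run ODE checks at 2000–3000 h.

## Known limitations

* Lumped distribution: no tissue-composition partitioning, no mechanistic
  kidney, no enterohepatic recirculation; transient CP-I kinetics depend on
  the nominal volumes even though steady-state ratios do not.
* Inhibitor disposition is linear and empirical; no transporter-mediated
  inhibitor uptake, time-dependent inhibition, or induction, so
  perpetrators with strong auto-inhibition or induction (e.g. chronic
  rifampicin) are out of scope.
* Renal OAT1/3 inhibition is not modeled; for perpetrators that also block
  renal secretion of the victim the engine will underpredict.
* Biliary (MRP2) inhibition is structurally present (the efflux clearance
  is a parameter) but no inhibition hook is wired to it by default.
* The genotype multipliers and virtual-inhibitor parameters are package
  design choices calibrated to or bracketing reported aggregate ratios;
  they are exposed as arguments rather than buried, and should be replaced
  when subject-level data are available.
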