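---
title: "Modelling the postprandial glucose-insulin-NEFA interplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the postprandial glucose-insulin-NEFA interplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glunefa)
```

## The scientific problem

After a meal, plasma glucose, insulin and non-esterified fatty acids
(NEFA) respond together: insulin released in response to the glucose load
suppresses adipose lipolysis (plasma NEFA falls), while circulating NEFA
in turn blunt insulin's suppression of hepatic glucose production and its
stimulation of peripheral glucose uptake. Clamp experiments quantify these
interactions one at a time under fixed glucose/insulin levels; translating
them into the dynamic postprandial situation requires a systems model.
`glunefa` implements a whole-body ordinary-differential-equation model of
this interplay, together with the simulation protocols (clamps, insulin
cascades, oral challenges), a weighted-least-squares calibration machinery
with ensemble-based uncertainty propagation, and the two analyses that
motivate the model: perturbations of NEFA metabolism and the decomposition
of postprandial glucose-flux regulation into NEFA and non-NEFA terms.

## Model structure

The system has 18 states. The glucose and insulin backbone is the Dalla
Man meal-simulation model: a two-compartment stomach plus gut with
nonlinear emptying, two glucose masses (plasma `Gp`, tissue `Gt`, both in
mg/kg), liver and plasma insulin masses (`Il`, `Ip`, pmol/kg), the
beta-cell secretion states (`Ipo`, `Y`) with a rate-of-change component,
the classical two-stage delayed insulin signal (`I1`, `Id`) and the remote
insulin compartment `X`. Renal excretion and insulin-independent uptake
(`Fcns`) are carried unchanged. The fixed parameters are the published
normal-subject values of that model.

Plasma NEFA (umol/L) obeys

\[ \frac{d\,\mathrm{NEFA}}{dt} = -J_A - J_B + J_C + J_D \]

with concentration-dependent uptake \(J_A = p_A\,\mathrm{NEFA}\),
insulin-dependent inhibition of lipolysis
\(J_B = p_B (I_{d7} - I_b)\,\mathrm{NEFA}\) (negative below basal insulin,
i.e. disinhibition), a constant net basal uptake \(J_C = p_C < 0\), and
spillover influx \(J_D = \mathrm{spill}\cdot J_{lpl}(TG)/V_{\mathrm{NEFA}}\).
Lipoprotein-lipase hydrolysis of circulating triglycerides is modelled as
insulin-stimulated and proportional to the TG concentration,
\(J_{lpl} = c_{lpl}\, TG\, I/(K_{lpl}+I)\), and the spillover fraction as
insulin-inhibited and bounded in \([0,1]\),
\(\mathrm{spill}(I) = s_{max} K_{sp}/(K_{sp}+I)\) with \(s_{max}\) anchored
so that \(\mathrm{spill}(I_b) = \mathrm{spill}_b\). TG itself is a
measured model *input* (interpolated by a fitted polynomial), not a state.

NEFA feeds back on glucose fluxes in two places. Endogenous glucose
production is linear in its regulators and floored at zero,

\[ EGP = k_{egp1} - k_{egp2} G_p - k_{egp3} I_{d2}
      - k_{egp4}\big(I_{po} + \mathrm{ins}_{inf}/\gamma\big)
      + k_{egp5} N_{d1}, \]

and insulin-dependent glucose uptake is Michaelis-Menten in `Gt` with an
insulin- and NEFA-dependent capacity,

\[ U_{id} = \frac{V_{max} G_t}{K_{m,uid} + G_t}, \qquad
   V_{max} = k_{uid1} + k_{uid3}\, I_{d3}/N_{d1}, \]

capturing the reciprocal relationship between circulating NEFA and
insulin-stimulated uptake.

### Design choices on under-determined points

* **Composition of the 18 states.** The delayed signals `Id2` (EGP),
  `Id3` (uptake) and `Id7` (lipolysis) are first-order relaxations toward
  their sources: `Id2` chains off the classical `I1 -> Id` cascade (making
  the EGP insulin delay three-stage), `Id3` and `Id7` relax directly
  toward plasma insulin, and `Nd1` toward plasma NEFA. The eighteenth
  state `Qing` accumulates the ingested glucose appearing in plasma
  (`dQing/dt = Ra * BW`); it closes the oral mass balance and yields the
  total-ingestion readout used for the fat-challenge simulations.
* **The infusion term in EGP.** The insulin infusion rate is divided by
  `gamma` (default: the portal transfer rate, 0.5/min), which converts a
  pmol/kg/min infusion into a portal-insulin-equivalent mass so it can sit
  beside `Ipo` inside one regulator term.
* **Units of `Gt`.** `Gt` is kept as the Dalla Man mass state (mg/kg)
  inside the Michaelis-Menten term; a concentration reading would only
  rescale `K_m,uid`, which is itself a free parameter.
* **`Nd1` floor.** The reciprocal `I_d3/N_d1` is floored at
  `nd1_floor = 1` umol/L; physiological NEFA never approaches zero, and
  the floor only guards pathological parameter draws during calibration.
* **EGP floor.** The linear EGP form can go negative under strong
  hyperinsulinemia; production is clipped at zero, the same convention the
  glucose-core model uses.
* **Clamped secretion.** Clamp protocols hold `Gp`, `Ip` and `NEFA`
  exogenously (states removed from integration, signals fed to all
  dependent terms; the clamped glucose derivative replaces `dG/dt` in the
  secretion equations). The portal state `Ipo` is additionally clamped to
  its basal value by default: with plasma insulin fixed by infusion, a
  freely responding beta-cell state under hyperglycemia would fully
  suppress EGP through the portal term and contradict the clamp
  physiology the model is meant to reproduce. Protocols can override the
  clamped `Ipo` value. Delay chains start from basal rather than being
  re-initialized to the clamp targets; the measurement windows (final half
  of 6-h clamps, final hour of 2-h clamps) leave time for them to settle.

## Numerical choices

Integration uses an adaptive Dormand-Prince RK45 with relative tolerance
1e-8 and absolute tolerance 1e-10 (native units), implemented in C++
because no ODE-solver package is available in this stack. The solver is
forced to step exactly onto every output time and every input breakpoint
(infusion steps, clamp-table knots), so output grids are hit without
interpolation and trajectories are bit-for-bit reproducible for identical
inputs. Fluxes are recomputed from the states at the output times.
Clamp averages are trapezoidal means over the measurement window; the
test suite checks that halving the output grid moves them by less than
0.01%.

The fasting initial state places the glucose-insulin core exactly at its
basal fixed point (basal secretion, liver/plasma insulin balance, and the
tissue-glucose root of `dGt/dt = 0`), `kegp1` is derived so that
`EGP(0) = EGPb` for every parameter set, and NEFA starts at `NEFA0`,
which is deliberately *not* a steady state (`pC < 0` plus spillover gives
a slow fasting drift). The shipped default `kuid1` is the basal-consistent
value that also zeroes the glucose-mass drift; during calibration `kuid1`
varies freely and the model then starts slightly off steady state, as in
the source physiology.

## Calibration and ensemble selection

The cost is the weighted sum of squared residuals
\(V = \sum_i (y_i - y^{obs}_i)^2/\sigma_i^2\) over all clamp averages and
meal time points (TG rows are inputs, not residuals). Optimization is
multi-start bounded L-BFGS-B on log-scaled parameters from Latin-hypercube
starts; every evaluated parameter vector is archived with its `V` and its
EGP-restricted sub-cost `V_EGP`. Selection keeps the sets within 120% of
the lowest cost, takes per-parameter extremes plus the minimum-cost set
(`S_ext`), and repeats the procedure after requiring the minimal
stomach-emptying rate `kra3 >= 0.009/min` (`S_sel`); the OFTT ingestion
dose is excluded from extremeness because it is unidentifiable at
sub-gram magnitude. Failed simulations score `Inf` rather than aborting a
start, and ensemble members are deduplicated at 1e-10 relative equality.
The minimum-cost set is always carried into both ensembles alongside the
per-parameter extremes — it is the set any downstream figure would show.

The parameter-recovery check in the test suite calibrates a reduced free
subset (the NEFA couplings `kegp5`, `kuid3` plus `pA`, `pB`, `kra3`,
`kn1`) with the remaining free parameters held at truth; this is a
runtime-scaling choice — one 50-start run over six parameters takes a few
minutes on one CPU — and the machinery itself accepts any subset of the
21 free parameters.

## The synthetic world

The calibration data the model was originally built on were digitized
from published figures and are not redistributable; the package therefore
ships a generator that emulates their structure from a known ground
truth:

* **Three-plateau NEFA clamp (6 h).** Hyperinsulinemic (70 uU/mL = 420
  pmol/L), euglycemic (85 mg/dL) clamps with NEFA plateaus of 766, 562
  and 51 umol/L; EGP and glucose uptake averaged over the final 3 h
  (3 EGP + 3 GU observations).
* **Six-arm 2-h clamp panel.** Hyperinsulinemic-euglycemic,
  hyperinsulinemic-hyperglycemic (200 mg/dL) and near-basal-insulin
  hyperglycemic (300 mg/dL) arms, each with and without a lipid+heparin
  infusion; NEFA follows linearly interpolated trajectories (suppressed
  under vehicle, rising under lipid); averages over the final hour. EGP
  is observed only in the near-basal-insulin group (2 EGP + 6 GU). The
  NEFA trajectory knots and the insulin levels of the vehicle/lipid arms
  are package choices within the published protocol's ranges.
* **Meal study.** A 100 g oral glucose challenge and a 40 g fat challenge
  over 6 h, sampled every 10 min to 120 min and every 30 min thereafter,
  optionally with no observations between 120 and 240 min (the source
  study's unobserved window). The OFTT TG input is a slow transient
  peaking around 3.5 h at roughly +600 umol/L over basal; the OGTT TG
  input is essentially flat.
* **Noise.** Independent Gaussian observation noise with relative
  standard errors of 3% (glucose), 8% (insulin, NEFA, TG) and 10%
  (EGP/GU averages) — implementer defaults, since the source SEs were
  graphical; the reported `se` column always equals the SD actually used.
  Population-mean data are emulated; no within-subject correlation or
  inter-individual variability is modelled, so a green recovery test
  establishes identifiability under idealized noise, not robustness to
  structured residuals.

The default parameter set doubles as the generator's ground truth. Its
fixed part is the published glucose-insulin values; its 21 free
parameters were hand-calibrated once, before the test suite was written,
to the qualitative physiology the source studies report: postprandial
NEFA undershoot followed by a post-absorptive overshoot, EGP rising and
glucose uptake falling across increasing NEFA plateaus under
hyperinsulinemia, monotone NEFA decline across an insulin cascade, and
insulin-mediated glucose homeostasis under NEFA perturbations. They are
not the original study's calibrated values (which are not published in
the main text) and carry no claim of quantitative equivalence.

## Analyses

**Perturbations.** `perturb_ogtt()` reruns the OGTT after either raising
the fasting NEFA concentration (`P_bas`; only the initial condition of
NEFA and its delayed copy change, so the calibrated `kegp1` anchor stays
put and elevated fasting NEFA raises EGP at t = 0, as it does
physiologically) or reducing the insulin sensitivity of lipolysis
(`P_lip`; `pB` is tuned by root-finding until the postprandial fall
`NEFA0 - min NEFA` shrinks by the requested fraction). Reported AUCs are
absolute trapezoidal areas over 0-360 min; relative changes are
`(AUC_pert - AUC_base)/AUC_base`.

**Contribution decomposition.** Along an OGTT trajectory the `Vmax`
excursion splits exactly into an insulin term
\(k_{uid3}(I_{d3}-I_b)/N_{d1,b}\) and a NEFA term
\(k_{uid3} I_{d3}(1/N_{d1} - 1/N_{d1,b})\); EGP suppression
\(EGP_b - EGP(t)\) splits into glucose, delayed-insulin, portal and NEFA
terms, each a deviation from its basal value (a package convention, since
the original decomposition is described only in supplementary material).
The relative NEFA contribution is the NEFA term over the sum of terms,
reported at the time of maximal absolute NEFA term, with times masked
where the total regulation is within 1% of its maximum magnitude (the
ratio is ill-defined near zero crossings).

## Limitations

* Only net plasma NEFA fluxes are modelled; tissue-resolved or absolute
  fluxes are out of scope, as is any direct stimulatory NEFA effect on
  beta-cell secretion.
* The many phenomenological delay compartments are weakly identifiable;
  the ensemble spread, not a formal identifiability analysis, is the
  uncertainty statement.
* The clamp insulin-infusion rates reported by the synthetic designs come
  from a quasi-steady approximation that assumes basal portal secretion.
* Under the default parameters the fat challenge produces no early NEFA
  dip (the sub-gram glucose ingestion raises insulin too little to beat
  the rising spillover influx); the late spillover-driven NEFA rise is
  reproduced. Real fat meals show a small initial decline.
* The Jelic-style LPL/spillover forms are reconstructions behind stable
  function interfaces (`jlpl_flux()`, `spill_fraction()`); swapping in a
  different published form only touches those two operations.
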