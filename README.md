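# glunefa

Whole-body modelling of the postprandial interplay between plasma
glucose, insulin and non-esterified fatty acids (NEFA) in humans.

After a glucose load, insulin suppresses adipose lipolysis and plasma
NEFA falls; circulating NEFA in turn blunt insulin's suppression of
endogenous glucose production (EGP) and its stimulation of
insulin-dependent glucose uptake (U_id). Clamp studies measure these
couplings at fixed glucose/insulin levels; `glunefa` embeds them in a
dynamic 18-state ODE model so they can be quantified during a meal. The
package is aimed at researchers in metabolic physiology and systems
biology who want to simulate clamp and oral-challenge protocols,
calibrate the model against flux and time-series data, and propagate
parameter uncertainty through the downstream analyses.

## The model in brief

The glucose-insulin backbone is the Dalla Man meal-simulation model
(stomach/gut transit with nonlinear emptying, plasma/tissue glucose,
liver/plasma insulin, beta-cell secretion, delayed insulin signals).
Plasma NEFA obeys

    dNEFA/dt = -J_A - J_B + J_C + J_D

with J_A = p_A·NEFA (uptake), J_B = p_B·(I_d7 - I_b)·NEFA
(insulin-inhibited lipolysis), J_C = p_C < 0 (basal net uptake) and
J_D = spill·J_lpl(TG)/V_NEFA (spillover of fatty acids liberated from
circulating triglycerides by lipoprotein lipase). NEFA feeds back through

    EGP  = k_egp1 - k_egp2·Gp - k_egp3·I_d2 - k_egp4·(I_po + ins_inf/γ) + k_egp5·N_d1
    U_id = Vmax·Gt/(K_m,uid + Gt),  Vmax = k_uid1 + k_uid3·I_d3/N_d1

where N_d1 is a delayed NEFA signal, and k_egp1 is derived so that
EGP(0) = EGP_b. TG is a measured input (polynomial-interpolated), not a
state. Full details, including every design decision on
under-determined points, are in `vignettes/glunefa-methods.Rmd`.

## Worked example

```r
library(glunefa)
params <- default_parameters()

# 100 g oral glucose tolerance test
conc <- plasma_concentrations(simulate_oral_challenge(ogtt_protocol(), params))

# hyperinsulinemic-euglycemic clamps at three NEFA plateaus
sapply(clamp1_design(params), function(p) unlist(simulate_clamp(p, params)[1:2]))

# NEFA-metabolism perturbation of the OGTT
perturb_ogtt(params, perturbation("P_bas", 1.5))$dAUC
```

Running `analysis/01_simulate_meals.R` and `analysis/02_clamps_and_cascade.R`
prints, for the shipped default parameter set:

```
OGTT: glucose 92 -> peak 209 mg/dL at 73 min, back to 101 at 360 min
      insulin peak 641 pmol/L; NEFA 400 -> nadir 88 at 132 min -> 486 at 360 min
...
Pattern check: across the NEFA plateaus (51 / 562 / 766 umol/L)
  EGP rises with NEFA  -> 0.23 < 0.74 < 0.95
  GU falls with NEFA   -> 7.76 > 2.97 > 2.67
Insulin cascade: end-of-step NEFA 391 -> 205 -> 82 -> 23 -> 6 umol/L ...
```

That is the package's core physiology: the postprandial NEFA undershoot
and post-absorptive overshoot; EGP rising (insulin resistance of the
liver) and glucose uptake falling (peripheral insulin resistance) as the
clamped NEFA level increases; and a monotone NEFA decline under stepwise
insulin. `analysis/04_perturbations.R` shows glucose homeostasis under
NEFA perturbations: for example, raising fasting NEFA by 50% changes the
glucose AUC by -0.3% while the insulin AUC rises by +3.1%
(`dAUC_NEFA = +0.035, dAUC_glucose = -0.0034, dAUC_insulin = +0.031`).

## Analysis workflow

The numbered scripts under `analysis/` are thin drivers over the package
functions; each writes its tables under `results/`:

1. `01_simulate_meals.R` — OGTT/OFTT trajectories and fluxes.
2. `02_clamps_and_cascade.R` — clamp-panel EGP/GU averages, insulin cascade.
3. `03_calibrate.R` — synthetic study, multi-start calibration,
   S_ext/S_sel ensemble selection.
4. `04_perturbations.R` — P_bas / P_lip perturbation grids and AUC changes.
5. `05_contribution.R` — relative NEFA contribution to U_id and EGP
   regulation, per parameter set, keyed by the EGP sub-cost V_EGP.

Because the original calibration datasets were digitized from published
figures and cannot be redistributed, `synthetic_data` generators
(`make_clamp_dataset()`, `make_meal_dataset()`, `synthetic_study()`)
emulate their structure from a known ground truth — the same machinery
the test suite uses for parameter recovery.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch — the oral challenges, the full clamp panel, the insulin
cascade, a seeded synthetic study with a multi-start calibration and
ensemble selection, and both analyses — logging a summary of each step,
and writes the results JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
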