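---
title: "A flow-limited PBPK model of lithium exposure in pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A flow-limited PBPK model of lithium exposure in pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lithium carbonate is a first-line mood stabilizer for bipolar disorder, a
condition whose onset in women often coincides with peak reproductive age.
Lithium crosses the placenta freely and is teratogenic, yet fetal lithium
levels cannot be measured directly. `lipbpk` predicts maternal organ and
fetal lithium concentrations under arbitrary oral dosing regimens, and
screens candidate regimens against the fetal exposure produced by a dosing
schedule documented to have caused birth defects (450 mg in the morning,
900 mg in the evening). A candidate regimen whose terminal-cycle fetal peak
or average exceeds the corresponding level of that pathological reference is
eliminated; regimens below both levels are classified acceptable.

## The model

The body is represented by eight well-mixed, constant-volume compartments:
plasma plus brain, thyroid, bone, GI tract, kidney, uterus and a
first-trimester fetus. Transport is **flow-limited**: blood leaving tissue
$i$ is in diffusion equilibrium with it, exiting at concentration $C_i/R_i$
where $R_i$ is the tissue-to-plasma equilibrium distribution ratio. A
generic tissue then obeys

$$\frac{dC_i}{dt} = \frac{Q_i}{V_i}\left(C_P - \frac{C_i}{R_i}\right),$$

which is the form used for brain, thyroid and bone. Four compartments carry
extra terms:

* **Uterus** — receives plasma inflow $Q_U C_P$ *and* fetal venous return
  $Q_F C_F/R_F$, and loses $(Q_U + Q_F)\,C_U/R_U$: the fetus is connected to
  the circulation only through the uterus (placental flow).
* **Fetus** — exchanges only with the uterus,
  $dC_F/dt = \tfrac{Q_F}{V_F}(C_U/R_U - C_F/R_F)$. First-trimester fetal
  renal clearance is neglected, so partitioning back to the uterine flow is
  the fetus's only elimination route.
* **Kidney** — carries the whole body's elimination, $-kk\,C_K/R_K$ with
  $kk$ = 20 mL/min (urinary clearance; the ~1% fecal route is neglected).
* **GI tract** — receives the oral input $G(t)$. A dose of $m_D$ mg of
  lithium carbonate delivered as a controlled-release tablet is modelled as
  **zero-order absorption**: $G(t) = m_D \cdot (8/300)\,/\,\Delta t$ mEq/min
  over a window of length $\Delta t$, zero outside it. Plasma collects the
  venous return of the six directly perfused tissues minus the total
  arterial outflow; absorption enters the plasma balance only indirectly,
  through the gut.

The state is stored as concentrations (the constant-volume assumption makes
amounts and concentrations interchangeable), and the system is linear —
$dC/dt = A\,C + g(t)$ with $g$ the absorption forcing. Linearity has three
consequences the test suite exploits: trajectories superpose (doubling every
dose doubles every concentration), the uniform state $C_i = R_i C_P$ is
stationary when dosing and clearance are off, and cycle-averaged
concentrations at the periodic steady state follow in closed form from the
flow balances.

## Parameters

The packaged physiology (`default_physiology()`, also shipped as
`inst/extdata/physiology_default.yaml`) describes a pregnant woman with a
first-trimester fetus:

| compartment | $V_i$ (mL) | $Q_i$ (mL/min) | $R_i$ |
|---|---|---|---|
| plasma | 5200 | — | — |
| brain | 1450 | 700 | 1.5 |
| thyroid | 13 | 60 | 1.5 |
| bone | 7273 | 272 | 1.5 |
| GI tract | 1650 | 1100 | 1.0 |
| kidney | 280 | 1240 | 1.0 |
| uterus | 1000 | 475 | 0.4 |
| fetus | 150 | 300 | 0.8 |

Bone volume is derived from 8 kg of bone at 1.1 g/mL (`bone_volume()`);
renal clearance is $kk = 20$ mL/min, at the lower end of the accepted
20–40 mL/min range; the drug conversion factor is 8/300 mEq lithium per mg
of lithium carbonate (a 300 mg tablet contains 8 mEq).

Two parameters deserve comment:

* **Fetal partition ratio $R_F = 0.8$.** No measured fetal partition data
  exist, and none are needed for screening: the model is linear, so every
  fetal concentration — candidate and reference alike — scales with $R_F$,
  and the classification is invariant under it (a property the test suite
  checks). $R_F$ is an ordinary, overridable parameter (`--rf` on the
  command line).
* **Absorption window $\Delta t = 240$ min.** Peak serum levels with
  controlled-release lithium occur 4–12 h after dosing; the 4-h lower end
  is the worst case for peak tissue concentrations and is the default,
  configurable per dose.

## Units

All internal computation uses {mEq, mL, min}, consistent with the mL-based
parameter table; a plasma level of 0.001 in internal units is therapeutic.
Reported concentrations are multiplied by 1000 and labelled **mEq/L**, the
scale on which clinical lithium levels (≈0.5–1.5) are quoted. Clinical
sources sometimes print such magnitudes with an mEq/mL label; this package
labels every output column and sidecar explicitly to keep the two scales
from being confused, and `read_physiology()` keeps the parameter table in
mL — do not convert the volumes to litres to "fix" the labels.

## Numerical choices

* **Integrator.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-12`; the
  system is small (8 states) and non-stiff at these parameters. Integration
  is *restarted at every absorption-window edge*, with $G$ held at its exact
  constant value inside each segment, so the discontinuous input is never
  smoothed across a step. Output lands on a grid of ≤ 1 min spacing.
* **Terminal profile.** Repeated dosing is run cycle by cycle from an
  all-zero state until, for every compartment, the relative change of both
  the within-cycle peak and the within-cycle average between consecutive
  cycles drops below `tolerance` (default 1e-6), or `max_cycles` (default
  60) is reached — non-convergence sets a flag rather than raising. With a
  plasma half-life near half a day, residual drift shrinks roughly
  four-fold per cycle and the default regimens converge in about 12 cycles.
* **Summary metrics.** Cycle averages use the trapezoid rule on the dense
  grid; peaks take the grid maximum refined by a local quadratic through
  the three nearest points. A single-dose plasma peak sits at the kink at
  the end of the release window, where the quadratic refinement is only an
  approximation — the refined peak time can shift by about a minute, well
  inside the reporting resolution. Halving the grid spacing moves reported
  peaks by well under 0.1%.
* **Closed-form cross-check.** At the periodic steady state the cycle
  average of every exchange flux is zero, giving
  $\bar C_P = \frac{\text{cycle dose}/T}{CL_\text{eff}}$ with
  $CL_\text{eff} = kk\,Q_K/(Q_K+kk)$ ≈ 19.68 mL/min, $\bar C_i = R_i \bar
  C_P$ for tissues without elimination, $\bar C_K = R_K\,\frac{Q_K}{Q_K+kk}
  \bar C_P$, and $\bar C_F/R_F = \bar C_U/R_U = \bar C_P$.
  `steady_state_average()` implements this and the suite requires the
  integrated terminal averages to match it within 1%. The independent
  oracle for full trajectories is the exact matrix-exponential solution of
  the piecewise-constant-input linear system, computed in the tests with
  `Matrix::expm` — deliberately a different route than the adaptive
  integrator it checks.
* **Ties in screening.** A candidate whose fetal peak or average lies
  within 1e-9 (relative) of a reference level is classified `at_reference`
  and treated as *not* acceptable; the reference regimen screened against
  itself is therefore never acceptable.

## Design decisions

* The reference levels are recomputed from the supplied physiology on every
  screening run, never cached, so overrides (e.g. `--rf`) propagate to both
  sides of the comparison.
* Multi-dose presets are evenly spaced by convention (12 h for 2 doses,
  8 h for 3, 6 h for 4); unequal-mass schedules such as 450/900 keep their
  stated clock offsets. The 300/300/500 "with meals" schedule is encoded at
  0/480/960 min: non-evenly-spaced dosing is out of scope, and its clock
  times are not documented. The 1000/300 preset administers the 1000 mg
  dose first, following the textual description of that regimen.
* The `single-900` preset lives on a 30-day cycle so that multi-day
  simulations of single-dose kinetics see exactly one administration.
* Bioavailability is implicitly 1, there is no first-order absorption
  option, and no food effects: the zero-order window is the formulation
  model.
* Screening uses fetal levels only. The maternal-brain average is reported
  as an informational column (therapy targets the brain) but no
  quantitative brain threshold exists to enforce, and no
  minimum-effective-dose check is applied.

## What the results do and do not show

Running the six study regimens to their terminal profile
(`fetal_exposure_table()`) reproduces the previously reported fetal maxima
essentially exactly (e.g. 1.434 mEq/L for 450/900) while the computed
averages come out 4–8% above the previously reported ones (1.016 vs 0.965
for 450/900). That pattern is expected: reported averages *differ* between
regimens with identical daily dose (0.867 / 0.860 / 0.886 for the three
1200 mg/day schedules), which a linear system at its exact periodic steady
state cannot produce — its averages depend on the daily dose only. The
values here are true converged terminal-cycle quantities (drift < 1e-6),
and comparisons against the reported table use a ±10% band. Likewise the
single-dose plasma half-life measured from the model is 10.7 h against a
reported "approximately 12 hours"; the one-pool estimate
$\ln 2\,(V_P + \sum_i V_i R_i)/CL_\text{eff} = 12.2$ h brackets the same
value from above, and the suite requires agreement within 15% of that
closed form.

The model deliberately omits: trimester-dependent growth of uterus and
fetus (parameters are fixed first-trimester values), inter-individual
variability, nonlinear binding or permeability-limited uptake, fecal
elimination, fetal renal clearance, and any pharmacodynamic/toxicity model
for the mother. Classifications are relative statements about a documented
pathological exposure under these assumptions — not clinical safety claims.

## Problem sizes

The default workloads are small by construction: a terminal-profile run is
roughly 12 cycles × 1441 grid points × 8 states, and the full six-regimen
exposure table completes in a few seconds on one core. The test suite and
the acceptance script rerun every quantity from scratch at these sizes.
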