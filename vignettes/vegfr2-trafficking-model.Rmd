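---
title: "A compartmental model of VEGFR2 trafficking and site-specific phosphorylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of VEGFR2 trafficking and site-specific phosphorylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`vegfr2traffic` simulates monolayers of endothelial cells exposed to
exogenous VEGF-A (the VEGF165 dimer, `V`), presented either free in the
medium ("soluble", Vs) or pre-bound to extracellular-matrix/heparin sites
(`M`; "immobilized", Vb). VEGF binds the receptor tyrosine kinase VEGFR2
(`R2`, assumed pre-dimerized) and the co-receptor Neuropilin-1 (`N1`).
Because NRP1 and the matrix engage the same heparin-binding domain of the
VEGF dimer, `M` and `N1` never occur in one complex; NRP1 and VEGFR2 couple
only through VEGF.

Receptor complexes move through five compartments: the extracellular space,
the cell surface, merged Rab4/Rab5-positive early endosomes, Rab11-positive
recycling endosomes, and a degraded pool (late/Rab7 endosomes and
lysosomes). Free and ligated receptor internalize; matrix-anchored
`M.V.R2` stays at the surface (it is tethered to the substrate). From early
endosomes a complex can recycle directly (Rab4 route), be transferred to
the Rab11 compartment and recycle from there, or be degraded. Degraded
species are retained as bookkeeping pools, which makes strict mass-balance
tests possible: total VEGFR2 across all compartments grows at exactly the
(calculated) production rate, and total VEGF is conserved.

Each VEGFR2-containing complex in a live compartment carries one of the
eight phosphorylation patterns of the three modeled tyrosines (Y951, Y1175,
Y1214). Phosphorylation and dephosphorylation are first order and
site-specific: ligated receptor phosphorylates at 1/s on each site, free
receptor not at all; dephosphorylation rates depend on the site, the
complex, and the compartment, with a fast (30/s) rate for free receptor
everywhere and for everything in Rab11 endosomes. Degradation erases the
phosphorylation state; every other transport step preserves it. Binding and
trafficking rates are independent of phosphorylation — a symmetry the test
suite exploits: summing the eight phospho-variants of any complex
reproduces the trajectory of a phospho-free reduced model to solver
accuracy.

The species list and all 557 unidirectional mass-action reactions are
*generated* from these composition rules rather than hand-listed
(`buildNetwork()`), and `validateNetwork()` re-derives the structural
counts: 97 species (3 extracellular, 34 surface, 27 in each endosomal
compartment, 6 degraded pools), 15 reversible binding-reaction types, and
120 reversible phosphorylation reactions. Two published aggregate counts
(277 total reactions, 31 trafficking reactions) follow a bookkeeping
convention we could not reconstruct; `validateNetwork()` reports our
equivalents (557 unidirectional; 131 phospho-replicated trafficking
reactions in 28 families) without asserting them.

## Units and geometry

All species are integrated in molecules per cm^2 of total cell surface.
Extracellular bulk concentrations map onto this basis through Avogadro's
number times the fluid depth (L/cm^2); endosomal bimolecular rates are
converted with the endosomal volume per unit surface area; surface-coupling
rates (per mol/cm^2) are divided by Avogadro's number. This single-unit
convention makes conservation laws exact and spares the right-hand side any
per-flux unit logic. `TimeCourse` accessors convert extracellular rows back
to molar for presentation.

The cell-geometry defaults are order-of-magnitude endothelial morphometry,
chosen once and exposed in the configuration: 1e5 cells/cm^2 (confluent
monolayer), 1e-7 cm^3 endosomal volume per cm^2 of surface for each
endosomal compartment, 0.5 cm medium depth (0.05 cm for the thin-layer
immobilized protocol of the low-dose presentation study), VEGF dimer mass
45 kDa. The matrix-site molar concentration is derived from the matrix mass
concentration through a configurable site molecular weight (default
30 kDa), chosen so that a 3 mg/mL gel provides 1e-4 M sites and therefore
binds >= 95% of the VEGF dose at the installed V-M affinity — consistent
with presenting immobilized VEGF as fully matrix-bound at time zero.

## Parameters

`defaultParameters()` carries the representative rate tables: binding
kinetics per pair and compartment class, trafficking rates per species form
(with the published tie structure: Rab4-route recycling equal for free and
ligated VEGFR2 and 100-fold slower for the NRP1 family; Rab11-route
recycling fast for the NRP1 family and 100-fold slower for VEGFR2;
free-receptor degradation 10-fold slower than ligated), and the
site-specific phosphatase rates. One printed value required interpretation:
the Rab11 recycling rate of ligated VEGFR2 appears with an impossible
exponent (1.4e+4/s) in its source row; we use 1.4e-4/s, the value its
stated 1/100 tie implies. Matrix-anchored receptor uses the surface-ligated
phosphorylation rates (immobilization does not alter intrinsic kinetics).

`applyStudyConfig()` specializes the base set to one of the experimental
columns: receptor numbers per cell, geometry, V-M kinetics, a 2.4-fold
degradation scale for the HUVEC studies, and the dose rule dividing the
ligated internalization rate by 6 above 50 ng/mL VEGF (at exactly
50 ng/mL the original rate is kept). Receptor production rates are then
*calculated*, not fitted: with the surface pool held at its measured
density the unligated surface/Rab4-5/Rab11 subsystem is linear, and the
unique production rate making it stationary equals the degradation outflow.
`steadyStateNoVegf()` initializes every simulation from this analytic
steady state and verifies the derivative is numerically zero; no nonlinear
root-finding is needed because VEGF is absent.

## Numerics

The phosphatase rates reach 75/s while trafficking rates go down to
1e-5/s, so the system is stiff. The default engine is `deSolve::lsoda`
with an analytically assembled sparse-stoichiometry Jacobian; an explicit
adaptive Runge-Kutta 4(5) engine is provided as an option, and a regression
test requires the two to agree to 0.1% on the reference scenarios.
Default tolerances are rtol 1e-8 and atol 1e-6 molecules/cm^2,
configuration-exposed; inside parameter-estimation cost evaluations the
tolerances are relaxed to 1e-6/1e-3 (the residuals are compared against
percent-scale, noisy observations) and the output grid is coarsened to one
minute. Finite-difference Jacobians in the optimizer use a step
(~1e-3 in log10-parameter units) well above the integration error, set via
`epsfcn`; without this the forward differences of weakly sensitive
parameters are dominated by solver noise and the fit stalls at bounds.

## Estimation by synthetic-data recovery

The original trafficking measurements behind the fitted rates (normalized
Rab4/5-vs-Rab11-vs-degraded receptor distributions, surface-NRP1 and total
receptor time courses, and their cost-function weights) are not available
in machine-readable form, so the estimation machinery is validated by
parameter recovery on synthetic data: `synthTraffickingObservations()`
simulates known "truth" parameters, samples the same observable set,
applies multiplicative Gaussian noise with a chosen CV, and renormalizes
each compartment-distribution triplet to sum to 100% exactly as the
colocalization data are normalized. `readObservations()` accepts the same
CSV layout, so users holding the original supplementary values can load
them directly.

The synthetic study emulates the three transfection arms of the underlying
colocalization experiment — VEGFR2+NRP1 (108,000 + 113,000 per cell),
VEGFR2 only (37,400 per cell), NRP1 only (113,000 per cell) — under
50 ng/mL soluble VEGF, with compartment distributions sampled at 10, 30
and 60 min and time courses at 5, 15, 30 and 60 min, unit weights, and a
steady-state penalty holding the no-VEGF surface fraction of VEGFR2 near
60% (weight 100, i.e. one percentage point of surface-fraction error
counts like one percentage point of data error; the published description
states the term's existence but not its weight). The three arms matter for
identifiability: with NRP1 present essentially all ligated VEGFR2 is
NRP1-bound, so the VEGFR2-only arm pins the ligated-VEGFR2 degradation
rate, and the NRP1-only arm pins NRP1's own degradation, otherwise masked
by the ternary-complex route. What recovery on these data does *not* show:
the synthetic generator shares the model's structural assumptions (merged
Rab4/5 pool, first-order kinetics, no spatial gradients), so passing
recovery demonstrates the estimator and identifiability under the model,
not model adequacy for real microscopy data.

`multistartLM()` draws starts log-uniformly (trafficking default 1e-4 to
1e-2/s), optimizes each with bounded Levenberg-Marquardt in log10-parameter
space (bounds 1e-5 to 1/s for trafficking; 1e-3 to 100/s is the documented
range for phosphatase fits), and accepts sets within a relative cost band
of the best (15% trafficking, 65% phosphorylation), with an optional
plausibility veto rejecting sets predicting fewer than 10
phospho-receptors per cell at peak (`peakPhosphoPerCell()`). The
acceptance experiment runs 20 seeded replicates at 10% noise with two
starts each and requires all six fitted rates within twofold of truth in
at least 80% of replicates.

```{r recovery-example}
arms <- traffickingArms()
obs <- synthTraffickingObservations(arms, noiseCV = 0.1, seed = 1)
prob <- traffickingFitProblem(obs, arms = arms)
ens <- multistartLM(prob, nStarts = 2, seed = 1001)
ens@best
```

## Scenarios, perturbations, sensitivity

`makeScenario()` reproduces each study column by name;
`applyPerturbation()` implements the interventions explored with the
model: NRP1 knockout, an NRP1-blind ligand (the VEGF165b isoform), VEPTP
knockdown (surface Y951/Y1175 dephosphorylation / 5), constitutively
active TCPTP (Y951/Y1214 dephosphorylation raised to 30/s everywhere), a
DEP-1-like surface phosphatase overexpressed by a chosen factor, equalized
endosomal dephosphorylation, and a matrix off-rate sweep. Phosphatase
perturbations act on ligated-receptor rates only — the free-receptor rates
already sit at the 30/s ceiling. All perturbations are pure functions of
the parameter set. `localSensitivity()` runs the published one-at-a-time
analysis: each parameter (tied families moving as a unit) is doubled and
halved, the absolute percent change of each output in the panel (pY1175,
pY1214, their ratio at 5/15/30 min, soluble and immobilized VEGF at 2 and
200 ng/mL) is computed against the unperturbed run, the two directions are
averaged, and outputs below a 1e-3 floor are excluded and counted.

## Design choices where the source left the design open

* **Species bookkeeping.** Free VEGF exists in both endosomal compartments
  (it is produced there by dissociation) but undergoes no reaction in
  Rab11 except rebinding; only the Rab4/5 pool degrades (1.2e-2/s). The
  degraded compartment holds six phospho-free pools. This is the only
  convention we found consistent with the published species count.
* **Ratio and peak conventions.** Peaks are maxima on a 1 s resampled grid
  over the first 60 min; ratio denominators below 1e-3% of baseline yield
  NA; "early times" for ratio statements is interpreted as the 2-10 min
  window. AUCs are trapezoidal in percent-minutes.
* **Immobilized initialization.** The full VEGF dose starts matrix-bound,
  remaining sites free; no pre-equilibration transient. Soluble protocols
  contain no matrix sites (a 3 mg/mL site pool would otherwise capture
  the soluble dose within seconds and erase the Vs/Vb contrast).

## Known limitations

The simulator reproduces the structural and conservation properties of the
model exactly, the analytic steady state (57.8% of VEGFR2 at the surface,
75.8% of NRP1), and the qualitative rerouting effects of NRP1 loss. Two
published emergent magnitudes are *not* reproduced under the printed rate
tables and are reported as computed: the fraction of ligated VEGFR2
phosphorylated after immobilized VEGF (we obtain ~80% at 5 min and ~58% at
30 min where ~33% and ~7% are reported) and the dominance of peak pY1214
over pY1175 (we obtain a ratio near 1, not above 2). The discrepancy is
structural, not numerical: at quasi-equilibrium a matrix-anchored surface
receptor with k_p = 1/s against a 0.043/s Y951 phosphatase is ~96%
phosphorylated, and any matrix-site pool concentrated enough to keep VEGF
immobilized re-anchors released receptor within seconds, so the 5-min
ligated pool is dominated by highly phosphorylated anchored receptor;
meanwhile the printed endosomal transfer/recycling rates fix the
Rab11:Rab4/5 occupancy of ligated receptor near 1.4 with Rab4/5-resident
receptor ~99% pY1175-occupied, flooring the late-time phosphorylated
fraction near 50%. Reproducing the published magnitudes would require run
conventions (matrix accessibility, Rab11 exit rates for ligated receptor)
that the available tables contradict, and we chose fidelity to the printed
values over agreement with the derived numbers. The affected readouts are
most sensitive to the matrix-site concentration and the Rab11 recycling
row, both configuration-exposed for users who wish to explore them.

Problem sizes throughout the test suite (30-60 min horizons, 20 recovery
replicates, two starts) are the package's own choices balancing statistical
resolution against a desk-scale run; each full-network simulation takes
well under a second.
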