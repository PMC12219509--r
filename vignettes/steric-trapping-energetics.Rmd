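---
title: "Models and methods: steric-trapping energetics, cooperativity, bicelle properties and amphiphile solvation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterictrap)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the parameters that matter, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Thermodynamic conventions

All free energies are in kcal/mol with R = 1.987e-3 kcal mol⁻¹ K⁻¹. The
folding free energy ΔG°(N−D) is the denatured-to-native free-energy
change, negative for a stable protein; "stability" is −ΔG. Three
temperatures recur, each carried explicitly by a `thermo_context()`:
297.65 K (24.5 °C, the bench temperature of the titrations; RT =
0.5914 kcal/mol, the cooperativity cutoff unit), 310 K (the MD
thermostat, used for solvation free energies), and 310.15 K (37 °C, the
chemical-denaturation incubation). `classify_cooperativity()` accepts an
explicit `rt_cutoff` (e.g. the rounded 0.6 kcal/mol) when reproducing
published calls made with the rounded constant.

## Steric-trapping binding models

The assay couples unfolding to the binding of the second of two mSA
molecules. Three isotherms cover the workflow:

* **First binding** — quadratic tight-binding solution of the 1:1 mass
  balance; valid at comparable protein and ligand concentrations, and
  exactly equal to the numeric mass-balance solution (asserted against a
  brute-force solver in the test suite at 1e-10 relative).
* **Competition binding** — the closed form used for FRET competition
  assays, implemented *exactly as printed*. This expression is an
  approximation to the exact coupled two-ligand equilibrium. We ship
  `solve_competition_equilibrium()`, an exact `uniroot`-based solver, as
  a diagnostic; the tests record a systematic deviation of roughly 0.09
  (fraction units, at P_T = 1, C_T = 2, [mSA] = 5, K_u/K_l = 0.5 in the
  tight-binding limit). The deviation is documented, not silently
  corrected, so fitted `k_ratio` values remain comparable with the
  published convention.
* **Second binding** — attenuation of the second mSA binding by the
  denaturation equilibrium K_D. The half-transition lies at
  [mSA] = K_d,biotin (1 + 1/K_D), which is why stable proteins require
  weak-affinity mSA variants: with ΔG = −7.1 kcal/mol at 297.65 K,
  K_D ≈ 6.1e-6, and only a pM-affinity variant (the default synthetic
  truth uses K_d,biotin = 2e-5 µM = 20 pM) places the transition inside
  the experimental 0–60 µM window.

Free-ligand approximation: total [mSA] is used as free ligand in the
competition and second-binding forms (the protein is sub-µM against µM
mSA); no depletion correction is applied.

Fitting (`fit_binding_model()`) is bounded least squares via
`minpack.lm::nlsLM` with equilibrium constants parameterized in log
space (structural positivity; the delta-method standard error of ΔG is
then exactly RT times the SE of log K_D). Plateaus are unbounded.
Initial guesses come from the signal extremes and the interpolated
half-transition concentration. The second-binding fit requires
K_d,biotin as a *fixed* parameter, mirroring the experimental workflow
in which it is measured independently; floating it against a single
isotherm is not identifiable.

## Cooperativity profiling

ΔΔΔG = ΔΔG(N) − ΔΔG(C) contrasts a mutation's destabilization of the two
subdomains; uncertainties combine in quadrature. The five-way partition
uses the printed interval conventions: the cooperative interval
−RT ≤ ΔΔΔG ≤ +RT is closed on both sides, the moderate classes are
half-open with their outer boundary inclusive (ΔΔΔG = 2RT is
"moderately localized"). The "narrow" scheme halves both cutoffs. The
partition is exhaustive — every finite value receives exactly one
label — and stable to ±1e-12 perturbations away from the cutoffs.
Classification is deliberately hard (no probabilistic softening near
cutoffs); the SE is reported alongside the label so users can judge
borderline calls themselves.

Burial classes follow the fractional solvent-accessible surface area of
the mutated residue: exactly 0 → buried; (0, 0.1] → partially buried;
above 0.1 → exposed. f_ASA is an *input*; the package does not compute
accessibility from structures. Rows with missing f_ASA are excluded
from burial-stratified analyses with a logged count.

Chow's test uses F = [(S_C − (S_1+S_2))/k] / [(S_1+S_2)/(N_1+N_2−2k)]
with k = 2 and an upper-tail F p-value; no multiple-testing correction
is applied. When both subgroup regressions are exact (S_1 + S_2 = 0,
e.g. noise-free synthetic panels) the statistic is undefined and the
result carries an explicit `degenerate` flag instead of a number; the
numerical threshold for "exact" is a relative tolerance of
`.Machine$double.eps^0.75` against the total sum of squares.

## Bicelle physical properties

* **q_eff** corrects the nominal lipid/detergent ratio for detergent
  partitioned into the aqueous phase at its critical bicelle
  concentration; fixed experimental CBCs of 6.5 mM (DHPC) and 2.5 mM
  (CHAPS) are provided as `default_cbc` and overridable everywhere.
* **Ideal-mixing CBC** is the mole-fraction harmonic mean of the
  component CMCs (reference values: DMPC 6e-6 mM, DHPC 15 mM, CHAPS
  6 mM); it always lies between the two CMCs.
* **Laurdan GP** = (I440 − I490)/(I440 + I490). Band intensities use the
  nearest sample within ±1 nm, otherwise linear interpolation; the
  lookup mode is recorded on the returned value.
* **Melting curves** fit r(T) = r1(T)·logistic((T − Tm)/B) + r2(T) with
  linear r1, r2 (both baselines slope with temperature, as DPH
  anisotropy data do). B is parameterized directly in °C with a
  positivity bound via log transform; the fit is unweighted least
  squares (per-point weights are not modeled). Tm is the inflection
  point.
* **SAXS thickness** uses L = 2π/Q from the second scattering maximum.
  The source convention was printed as "Q = 2p/L (p = h/λ)", which is
  dimensionally inconsistent for Q in Å⁻¹; the package adopts the
  standard Bragg-like relation and records that choice here.

## Amphiphile contact dynamics and solvation free energy

The module consumes per-molecule heavy-atom contact-count series (the
upstream convention: heavy atoms within 5 Å of the protein, or of a
partner amphiphile for bulk pairs) — it does not read raw trajectories.

**Events.** A contact event is a maximal run of in-contact frames in
which non-contacting gaps no longer than a threshold are absorbed. The
recommended threshold is the bulk amphiphile conformational relaxation
time estimated from `rmsd_lag()` (the plateau lag of the time-lagged,
superposed conformational RMSD); it is an explicit argument everywhere.

**Autocorrelation.** c(τ) averages q(t)·q(t+τ)/q(t)² over origins t with
q(t) > 0 (division guard) and t+τ inside the trace. Two deliberate
choices, both exposed as arguments:

* `beyond_event = "event"` (default): the count series of an event
  vanishes outside the event, so c(τ) measures contact persistence and
  decays to zero for transient contacts. The alternative `"trace"` reads
  q(t+τ) from the full trace; rebinding after the event then contributes
  and c(τ) plateaus near the equilibrium bound fraction, which makes the
  1/e residence time undefined for fast-rebinding systems. The
  event-limited form is the one under which the 1/e definition is
  meaningful.
* `weighting = "origin"` (default) pools valid origins across events.
  For exponential dwell times this makes c(τ) the residual-lifetime
  survival function exp(−k_off τ), so the 1/e lag estimates 1/k_off —
  the property the whole analysis relies on, and the property the test
  suite checks by simulation. The literal equal-weight-per-event mean
  (`weighting = "event"`) down-weights long events and decays markedly
  faster (its 1/e lag underestimates 1/k_off by roughly half for
  exponential dwells); it is retained for comparison.

**Residence time.** τ_R solves c(τ_R) = 1/e. The default route fits a
triple-exponential with simplex-constrained amplitudes (Σa = 1, a ≥ 0)
and log-space time constants, multi-started from curve-crossing-based
and span-based initializations with the best SSE kept; if no
three-component start converges the fit falls back to two and then one
component, flagged. The root is then found by bracketed `uniroot` on the
fitted curve. Raw-curve linear interpolation is available for
diagnostics. Curves that never reach 1/e return a censored result
carrying the largest examined lag as a lower bound.

**Solvation free energy.** ΔG°Solv = −RT ln(τ_R,P·L / τ_R,L·L) at 310 K,
negative when amphiphiles prefer the protein surface. The ensemble
formulation (exponential average of per-site free energies) and the
mean-residence-time formulation are algebraically identical — the
exponentials cancel — and both are implemented separately in
`solvation_dg_sites()` so the identity can be asserted numerically
(the suite checks 1000 random site sets at 1e-12 relative).

**RMSF** superposes each frame onto the mean structure (two-pass, so the
reference is self-consistent) before computing per-atom fluctuation.
Superposition absorbs six rigid-body degrees of freedom, shrinking the
apparent isotropic fluctuation by about sqrt(1 − 6/(3N)); the
`superpose = FALSE` escape hatch exists for closed-form checks and
pre-aligned input.

## Three-state chemical denaturation

The observable is the population-weighted average of three linear state
baselines with unfolding equilibrium constants
K = exp(−(|ΔG| − m[D])/RT). Two sign conventions collide in the source
material: the printed equilibrium-constant expressions combined with the
negative reported ΔG values would favor unfolded species at zero
denaturant. The package adopts the physically consistent reading — the
constants are *unfolding* constants built from |ΔG|, while reported
parameters keep the folding (negative) sign so landscape levels match
the published convention (U = 0, I = ΔG(I−U), N = ΔG(N−I) + ΔG(I−U)).
The reported "total" is the N–U sum.

Evaluation is log-sum-exp throughout, so exponents of several hundred
(steep m-values, high denaturant) cannot overflow; populations sum to
one at 1e-12 everywhere. Fitting supports the two published workflows:
m-values fixed at previously determined values (the thicker-bilayer
case, m = 2.0 and 7.2 kcal mol⁻¹ M⁻¹) or floated (the thinner-bilayer
case). Free energies are fitted as log-magnitudes. Degenerate designs
fail loudly: titrations that cover only denaturant above both midpoints
error before fitting (when a truth-informed initialization reveals it)
or warn when fitted midpoints fall outside the titrated range, and
midpoint inversion (C_m(N−I) ≥ C_m(I−U)) raises a diagnostic suggesting
a two-state treatment rather than silently switching model. With m
fixed at values differing from the generating ones, the fitted ΔG
absorbs the mismatch — this is a property of the m-value convention
itself, and the suite quantifies it rather than hiding it.

Folding- and unfolding-direction points are pooled before fitting (path
independence after the stated equilibration).

## Synthetic-data generators

The study's raw data (plate-reader fluorescence, EPR, SAXS images) are
not deposited in machine-readable form, so seedable generators are the
canonical test inputs, with published parameter values as default
truths. Design choices:

* Noise is additive, independent, homoscedastic Gaussian everywhere
  (recorded in each output's `spec`); per-point noise magnitudes are not
  published, so the defaults (σ = 1% of the signal dynamic range for
  titrations, σ = 0.005 anisotropy units for melting curves) are the
  package's own choice of a realistic plate-reader/fluorometer scale.
* Grids mirror the experimental designs: log-spaced 0–60 µM mSA with a
  zero point, linear 1–5 M GdnHCl, 3.0–42.5 °C temperature sweeps.
* Contact traces are two-state continuous-time processes with
  exponential dwells, discretized to the frame grid (frame midpoint
  convention); bound frames carry constant or zero-truncated Poisson
  counts. Molecules start bound, so k_on = 0 yields exactly one event
  per molecule. A warning flags frame intervals coarser than the mean
  bound dwell (aliasing).
* All generators seed a local RNG and restore the caller's stream;
  identical (seed, spec) pairs are bit-identical.

What the generators do *not* emulate: instrument artifacts
(photobleaching, inner-filter effects, detector drift), correlated or
heteroscedastic noise, multi-site contact-count correlations, and
non-exponential dwell-time distributions. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to every pathology of real data.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own benchmark conditions: parameter-recovery
grids of 6 stabilities spanning −8 to −3 kcal/mol; 200 seeded replicates
at 1% noise for the binding bias check; 1000 random site sets for the
solvation identity; contact closures at ~1000–3700 events (40–80
molecules, 2000–6000 ns at 0.5 ns frames); 2000 null replicates for the
Chow type-I rate; 100 seeds for the melting T_m calibration. These sizes
put Monte-Carlo error comfortably inside each check's tolerance while
keeping a full run in tens of seconds.

## Known limitations

* The competition closed form is reported as printed; quantitative
  K_unlabel estimates inherit its documented bias relative to the exact
  coupled equilibrium.
* No global multi-curve fitting across variants; each isotherm is fitted
  independently.
* The three-state model assumes exactly one intermediate; the package
  diagnoses, but does not fit, two-state or four-state alternatives.
* Residence-time censoring is reported but not modeled (no survival
  regression on censored τ_R values).
* No structure parsing, accessibility computation, raw SAXS modeling, or
  trajectory reading; those belong to upstream tools.
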