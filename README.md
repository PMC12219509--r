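# sterictrap

Quantitative analysis machinery for membrane-protein folding
thermodynamics. The package is written for biophysicists who measure the
stability of helical membrane proteins by **steric trapping** — coupling
the spontaneous unfolding of a doubly biotinylated protein to the binding
of two bulky monovalent streptavidin (mSA) molecules — and who relate
those stabilities to the physical properties of the host bicelle and to
the solvation dynamics of lipids and detergents seen in molecular
dynamics (MD) simulations.

## What it computes

**Steric-trapping binding models.** The first, unhindered mSA binding
follows the quadratic tight-binding isotherm

    F = A1 * [(P_T + [mSA] + K_d) - sqrt((P_T + [mSA] + K_d)^2 - 4 P_T [mSA])] / (2 P_T) + A2

while the second binding is attenuated by the denaturation equilibrium
(K_D = [D]/[N]):

    F = (F_inf - F_o) / (1 + (K_d,biotin + K_d,biotin/K_D) / [mSA]) + F_o,
    dG_N-D = -RT ln(1/K_D)

`fit_binding_model()` fits all three isotherms (first, competition,
second) with positivity-safe log parameterization and asymptotic
standard errors; `dg_from_kd()` / `kd_from_dg()` convert between K_D and
the folding free energy. A brute-force coupled-equilibrium solver
(`solve_competition_equilibrium()`) ships as a diagnostic for the
competition closed form.

**Cooperativity profiling.** For a mutation measured against both
biotin-pair constructs, `compute_dddg()` forms
ΔΔΔG = ΔΔG(N) − ΔΔG(C) and `classify_cooperativity()` applies the five-way
partition with cutoffs at ±RT and ±2RT (a narrow ±RT/2, ±RT scheme is
available). `chow_test()` compares regression slopes between burial
strata with the classical two-regression F statistic.

**Bicelle properties.** `q_eff_fixed_cbc()` (effective lipid/detergent
ratio), `cbc_ideal_mixing()` (harmonic CMC mixing), `gp_laurdan()`
(generalized polarization), `fit_melting()` (sigmoid T_m with sloped
baselines) and `thickness_from_peak()` (L = 2π/Q).

**Amphiphile solvation dynamics.** From per-molecule contact-count time
series: `detect_contact_events()`, `contact_autocorr()`,
`fit_triple_exp()`, `residence_time()` (the 1/e lag), and
`solvation_dg()`:

    dG_Solv = -RT ln(tau_R,protein-amphiphile / tau_R,amphiphile-amphiphile)

plus `rmsd_lag()` / `rmsf()` for conformational relaxation and
fluctuation of coordinate tracks.

**Three-state folding.** `fit_three_state()` fits GdnHCl titrations to
the N ⇌ I ⇌ U model

    Y_obs = (Y_N + Y_I K_N-I + Y_U K_N-I K_I-U) / (1 + K_N-I + K_N-I K_I-U),
    K = exp(-(|dG| - m [D]) / RT)

with fixed or floated m-values, and `landscape_summary()` reports state
levels relative to the unfolded reference.

**Synthetic data.** Every input class has a seedable generator
(`sim_binding_titration()`, `sim_denaturation_titration()`,
`sim_melting_curve()`, `sim_contact_traces()`, `sim_mutant_panel()`)
with known ground truth, so every fitting and classification stage is
testable without any external data.

## Worked example

Simulate a second-binding isotherm for a protein of stability
−7.1 kcal/mol probed with a weak-affinity mSA variant
(K_d,biotin = 20 pM), then fit it back:

```r
library(sterictrap)
ctx <- thermo_context()            # 297.65 K bench conditions
truth <- list(k_denat = kd_from_dg(-7.1, ctx), kd_biotin = 2e-5,
              f0 = 1, f_inf = 0.1, protein_total = 1)
sim <- sim_binding_titration("second", truth, n_points = 12,
                             noise_sigma = 0.01, seed = 7)
fit <- fit_binding_model(sim$titration, "second",
                         fixed = list(kd_biotin = 2e-5), context = ctx)
fit
#> Steric-trapping 'second' binding fit (12 points, RSS = 0.00125)
#>          estimate        se
#> k_denat 6.501e-06 3.253e-07
#> f0      9.999e-01 6.141e-03
#> f_inf   1.246e-01 9.815e-03
#> dG_N-D = -7.06 +/- 0.03 kcal/mol (T = 297.65 K)
```

The fitted denaturation constant K_D ≈ 6.5e-6 corresponds to a folding
free energy of −7.06 ± 0.03 kcal/mol — within two standard errors of the
−7.1 kcal/mol used to generate the data. The same session can summarize
a three-state landscape and classify cooperativity calls:

```r
landscape_summary(three_state_params(-5.4, -26.4, 2.0, 7.2))$levels
#>     U     I     N
#>   0.0 -26.4 -31.8        # kcal/mol relative to the unfolded state
classify_cooperativity(c(-1.4, 0.3, 0.9), ctx)
#> [1] localized_C  cooperative  moderately_localized_N
```

A YAML-driven front end (`run_pipeline()`, with a thin Rscript wrapper
in `inst/cli/sterictrap-cli.R`) chains simulate/fit/classify/report
stages into reproducible, logged runs.

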