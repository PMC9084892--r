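# foldbind

Quantitative analysis of von Willebrand factor (VWF) A1-domain stability
and GPIbα binding, for protein biophysicists studying how the
O-glycosylated N- and C-linkers flanking A1 regulate its conformational
equilibrium and receptor affinity. The package implements five analysis
stages as composable R functions, plus seeded synthetic-data generators
that emulate each instrument modality so every stage is testable without
instrument files:

1. **Three-state urea unfolding** (`fit_global_three_state`) — global
   linear-extrapolation fits of fluorescence-ratio (FIR = I350/I330)
   denaturation curves to
   FIR(C) = Σⱼ (bⱼ + sⱼC)·pⱼ(C) with Boltzmann populations
   pⱼ ∝ exp(−ΔGⱼ/RT), ΔGⱼ(C) = ΔGⱼ⁰ + mⱼC over states j ∈ {N, I, D};
   slopes and m-values shared across constructs, intercepts and
   free-energy gaps per construct. Reports ΔG_I–N, C_urea I–N, and
   construct differences with propagated errors.
2. **Thermal ramps** (`melting_analysis`) — Savitzky–Golay dFIR/dT,
   transition/shoulder detection, local-logistic Tm refinement, and
   backscatter aggregation-onset detection.
3. **BLI kinetics** (`fit_global_kinetics`) — double referencing and
   global one-site fits (single kon/koff, per-sensor Rmax) with
   heterogeneity (lack-of-fit) diagnostics and NaCl fold-change
   summaries.
4. **ITC** (`fit_one_site_itc`) — one-site isotherm fits of injection
   heats under the displacement-dilution convention, with
   ΔG = −RT ln K, TΔS = ΔH − ΔG decomposition and an
   enthalpy–entropy-compensation rank check.
5. **HDX-MS** (`difference_map`) — peptide-level relative uptake,
   coverage/redundancy, and pairwise construct difference maps with the
   strict >0.7 Da significance threshold and ±0.15 Da repeatability
   propagation.

## Worked example

```r
library(foldbind)

# synthetic four-construct urea panel at the study design
g <- gen_urea_curves(noise_sd = 0.005, seed = 1)
fit <- fit_global_three_state(g$curves)
print(fit)
#> <three_state_fit>
#>   shared: sN=0.01029 sI=0.001476 sD=-0.05395  mI=-2.019 mD=-3.96  (|mI|=2.019 |mD|=3.96)
#>   residual RMS: 0.003948 FIR (96 obs, 25 parameters)
#>   A1 short         dG_I-N = 2.50 +- 0.20 kcal/mol,  C_urea I-N = 1.24 M
#>   A1+OGly+C        dG_I-N = 2.73 +- 0.22 kcal/mol,  C_urea I-N = 1.35 M
#>   A1+OGly+N        dG_I-N = 4.53 +- 0.35 kcal/mol,  C_urea I-N = 2.25 M
#>   A1+OGly+N+C      dG_I-N = 4.76 +- 0.36 kcal/mol,  C_urea I-N = 2.36 M

cc <- compare_constructs(fit, "A1+OGly+N", "A1 short")
cc$ddG
#> [1] 2.033949
```

The fit recovers the free-energy gap between the native and intermediate
states per construct: here the N-linker construct sits ~2 kcal/mol above
the short construct, which at 20 °C corresponds to an
exp(2/RT) ≈ 31-fold suppression of the intermediate-state population —
the thermodynamic signature of N-linker stabilization. `C_urea I-N` is
the urea concentration at which N and I are equally populated.

## Analysis workflow

Numbered drivers under `analysis/` regenerate the full study from
scratch and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic datasets, all 5 modalities
Rscript analysis/02_fit_unfolding.R   # global three-state fit, ddG table
Rscript analysis/03_thermal.R         # Tm and aggregation-onset table
Rscript analysis/04_kinetics.R        # BLI panel, NaCl fold changes
Rscript analysis/05_itc.R             # thermodynamic panel, compensation
Rscript analysis/06_hdx.R             # coverage and difference maps
```

Each script prints what it finds; for example `04_kinetics.R` ends with
the electrostatic-steering summary
`10 vs 150 mM NaCl, 4 constructs: mean on-rate increase 17.2-fold
(geometric; arithmetic 17.3)`.

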