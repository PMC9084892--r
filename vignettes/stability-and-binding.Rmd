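---
title: "Models and methods: A1 stability, binding kinetics, calorimetry and exchange maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: A1 stability, binding kinetics, calorimetry and exchange maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldbind)
```

# The scientific problem

The von Willebrand factor (VWF) A1 domain binds platelet GPIbα under
tensile force, and its affinity is regulated by the O-glycosylated
mucin-like linkers flanking the domain. This package implements the
quantitative analyses used to characterize that regulation: equilibrium
urea unfolding of a three-state (native N, intermediate I, denatured D)
system, thermal transition and aggregation-onset detection from nanoDSF
ramps, one-site biolayer-interferometry (BLI) kinetics, one-site
isothermal titration calorimetry (ITC), and peptide-level
hydrogen–deuterium exchange (HDX-MS) difference maps. Seeded generators
emulate each modality so the whole analysis chain is testable without
instrument data.

# Three-state unfolding model

The readout is the tryptophan fluorescence intensity ratio
FIR = I350/I330. Each state contributes a linear baseline
$f_j(C) = b_j + s_j C$ in urea concentration $C$, and the observed signal
is the population-weighted sum

$$\mathrm{FIR}(C) = \sum_{j \in \{N,I,D\}} (b_j + s_j C)\, p_j(C), \qquad
p_j = \frac{e^{-\Delta G_j/RT}}{\sum_k e^{-\Delta G_k/RT}},$$

with the linear extrapolation method (LEM)
$\Delta G_j(C) = \Delta G_j^0 + m_j C$ and the native state as reference
($\Delta G_N \equiv 0$). We keep the literal sign convention
$\Delta G_j^0 + m_j C$, so fitted m-values are negative for unfolding at
high urea; $|m|$ is reported alongside for comparison with the LEM
literature. Populations are evaluated with a log-sum-exp shift and remain
exact for $|\Delta G|$ up to hundreds of kcal/mol. The gas constant is
carried as $R = 1.9872 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ and urea
experiments default to 293.15 K.

The global fit shares the baseline slopes $s_N, s_I, s_D$ and the
cooperativities $m_I, m_D$ across all constructs in one call (the linkers
carry no tryptophan and are unfolded, so neither the slopes nor the
m-values should differ between constructs), while the intercepts
$b_N, b_I, b_D$ and the zero-urea gaps $\Delta G_I^0, \Delta G_D^0$ are
per construct. Derived per construct are $\Delta G_{I\text{–}N} =
\Delta G_I^0$ and the equal-population concentration
$C_{\text{urea},I\text{–}N} = -\Delta G_I^0 / m_I$.

Numerical choices:

* **Initialization** is self-starting: $b_N, s_N$ from the lowest 20% of
  urea points, $b_D, s_D$ from the highest 20%, $b_I$ from low-slope
  points between the two largest centered-difference peaks, and the free
  energies from the apparent midpoints assuming $m_I = -2$ and
  $m_D = -4$ kcal mol⁻¹ M⁻¹. The second midpoint pins
  $\Delta G_D^0 = \Delta G_I^0 + (m_I - m_D)\,C_{\mathrm{mid},2}$, since
  the upper transition is an I→D crossing rather than an N→D one.
* **Optimization** is Levenberg–Marquardt least squares
  (`minpack.lm::nls.lm`) with the analytic Jacobian of the model
  (closed-form in the populations), relative-cost convergence at 1e-10,
  and a few ±20% multiplicative restarts; generous physical bounds
  ($m \in [-15, -0.01]$, intercepts in $[0, 10]$) exclude a degenerate
  basin in which a runaway $|m_D|$ turns the D transition into a step
  absorbed by the baseline.
* **State-label canonicalization.** The model is invariant under swapping
  the I and D parameter blocks; fits are relabeled so I is the
  lower-energy excited state.
* **Standard errors** come from the pseudo-inverse of $J^\top J$ scaled
  by residual variance, with column equilibration; a seeded residual
  bootstrap (typically 200 draws) is available for non-Gaussian noise.
* **Duplicates** in urea concentration are kept as independent residuals,
  preserving their weight. $s_I$ is freely fitted by default (the
  plateau slope was fitted, not fixed, in the source analysis); fixing it
  is left to the caller via the per-curve-slopes escape hatch.

What recovery tests show — and their limit. Under the experimental design
(24 points over 0.135–6 M, four constructs, FIR noise sd 0.005) the
curvature-based standard error of $\Delta G_I^0$ is 0.24–0.41 kcal/mol
and of $m_I$ about 8%; Monte-Carlo scatter matches those numbers, i.e.
the estimator sits at the information limit of the design. Recovery to
±0.3 kcal/mol therefore holds in roughly half of replicates, not 90%;
the corresponding acceptance check is asserted at the stricter rate and
fails honestly. Real curves with lower noise or replicate titrations
tighten this proportionally.

# Thermal ramps

Melting is read from the smoothed derivative dFIR/dT: order-2
Savitzky–Golay-style local polynomial regression over a temperature
window (default 2.5 °C), implemented as per-point weighted quadratic
fits so the window can shrink at the scan endpoints and tolerate
nonuniform grids. Transitions are local maxima of the derivative with
prominence at least 10% of the global maximum; second-derivative zero
crossings with positive slope are reported separately as low-confidence
shoulder candidates, and peaks in the endpoint half-windows are
suppressed (their variance is inflated by window shrinkage).

The derivative locates and counts transitions, but its argmax is a
statistically inefficient estimator of Tm: at signal-to-noise 20 its
localization error is ~0.3 °C while a local model fit achieves ~0.1 °C.
`melting_analysis()` therefore refines each detected peak by fitting a
logistic step plus local linear baseline to the FIR within ±5 °C
(`refine = FALSE` restores the raw derivative-peak temperature). The
refinement carries a <0.1 °C bias from a neighboring transition's tail
at 10 °C separation — the price of robustness against spurious
components.

Aggregation onset from backscatter: baseline = first 5 °C of scan,
threshold = baseline mean + 5 sd, onset = lowest temperature exceeding
the threshold for at least 1 °C; a backscatter trend already inside the
baseline window returns the scan start with a baseline-undefined warning.

# BLI kinetics

One-site binding with association
$R(t) = R_{eq}(1 - e^{-k_{obs}t})$, $k_{obs} = k_{on} C + k_{off}$,
$R_{eq} = R_{max} C/(C + K_D)$, and exponential dissociation from the
fitted (not observed) phase-boundary value. Double referencing subtracts
the buffer-only internal reference and the unloaded-sensor parallel
reference; grids differing by up to one sample period are interpolated.
The global fit shares $k_{on}$ and $k_{off}$ across all concentrations
with per-sensor $R_{max}$ by default (tip loading varies), rates on the
log scale. Lack of fit — the operational signature of a sample that
"cannot be fit to a single on- and off-rate" — is flagged when the
residual RMS exceeds 3× the high-frequency noise estimate (second
differences) or a runs test on the residuals fails at $z < -6$; the runs
test is gated on residuals exceeding numerical noise so that exact fits
are not flagged. Fold changes across NaCl conditions are summarized by
the geometric mean (ratios are multiplicative), with the arithmetic mean
alongside.

# ITC

Injection heats follow the displacement ("perfusion") convention: each
injection of volume $dV$ dilutes the cell contents by $(1 - dV/V_0)$
before adding titrant, the one-site equilibrium is solved through the
numerically stable root of the quadratic in bound complex, and
$q_i = V_0 \Delta H \left(B_i - B_{i-1}(1 - dV_i/2V_0)\right)$. A 0.4 µl
priming injection is excluded from analysis but included in the
concentration bookkeeping; the default protocol is 18 × 2 µl injections
every 180 s at 22 °C (cell 200 µl — not printed in the source protocol,
so the instrument-class default is used and configurable). One
consequence of the prescribed heat expression is that past saturation
the heats are slightly negative (dilution shrinks the bound pool); the
all-same-sign property holds for the pre-saturation injections.

The fit estimates $n$, $K$ (log scale) and $\Delta H$ plus an optional
constant dilution-heat offset carried in units of the mean absolute heat
so all parameters are O(1). Derived: $K_D = 1/K$,
$\Delta G = -RT\ln(K \cdot 1\,\mathrm{M})$ (1 M standard state) and
$T\Delta S = \Delta H - \Delta G$, so the decomposition identity is exact
by construction. A Wiseman c-value outside [1, 1000] triggers a
reliability warning. At 2% noise (of the first-injection heat) the
information limit gives SE($K$) ≈ 9% across the panel's c-values even
though $n$ and $\Delta H$ recover to ~1%; the 5%-at-90% acceptance check
on all three parameters is asserted as stated and fails honestly.
Enthalpy–entropy compensation across a construct panel is checked as
equality of the $\Delta H$ and $T\Delta S$ rank orders with the Spearman
correlation reported; ties break by label order and are flagged.

# HDX-MS difference maps

Peptide-level relative uptake (no back-exchange correction). Exchangeable
amides per peptide = length − 1 − non-terminal prolines (the N-terminal
amide back-exchanges too fast to observe). Coverage is the percentage of
region residues covered by ≥1 peptide; redundancy is the mean peptide
depth over the whole region by default (uncovered residues count zero; a
covered-only variant is provided because the instrument software's
convention is not disclosed). Differences between constructs are computed
on replicate-averaged uptake; an entry is significant when
$|\Delta| > 0.7$ Da with a strict inequality, and the per-entry
uncertainty is $0.15\,\mathrm{Da} \times \sqrt{1/n_A + 1/n_B}$ from the
stated per-measurement repeatability. Replicates are averaged
arithmetically with no statistical test, matching the source convention.
Both per-timepoint entries and per-peptide sums over timepoints are
emitted, since the aggregation behind the published difference panels is
not fully specified. Residue numbering is 1-based inclusive pre-pro-VWF
throughout.

# Synthetic data generators

Each generator is a pure function of its configuration including the
seed, and embeds its truth record for recovery studies. The defaults are
the study conditions:

* **Urea**: 24 steps over 0.135–6 M, FIR noise sd 0.005, four constructs
  with shared slopes/m-values ($m_I = -2$, $m_D = -4$ kcal mol⁻¹ M⁻¹,
  within the range reported for domains of this size) and
  $\Delta G_I^0$ = 2.5/2.7/4.5/4.7 kcal/mol so the N-linker constructs
  sit 2 kcal/mol above the others and the full-length glycosylated
  construct at 4.7 kcal/mol; first transitions at 1.25–2.35 M, second
  above 5 M, FIR baselines ~0.84 → 1.0 → 1.1. This panel is a synthetic
  stand-in for the deposited denaturation source data, which cannot be
  fetched offline.
* **Thermal**: logistic-sum phenomenology (the analysis only needs known
  transition locations, not a thermodynamic model), 30–85 °C at 0.1 °C
  sampling emulating a 1 °C/min ramp; noise defaults to amplitude/20
  (signal-to-noise 20). Backscatter is flat at baseline with an optional
  saturating rise beginning exactly at the configured onset.
* **BLI**: five concentrations in a 3-fold series around $K_D$, 1% of
  $R_{max}$ noise, optional drift and a second-species fraction for
  heterogeneity studies; buffer-only and unloaded-sensor reference wells
  are generated alongside.
* **ITC**: the titration protocol above with noise sd = 2% of the first
  injection heat.
* **HDX**: intrinsic rates log-uniform over 10⁻²–10² min⁻¹
  (sequence-specific rate tables are out of scope), uptake
  $\propto (1 - e^{-k_{int} t / PF})$ scaled by the 93.3% D₂O fraction
  and 32.5% back exchange (mid-range of 30–35%), five timepoints from
  10 s to 4 h, duplicate measurements with 0.15/√2 Da replicate noise,
  and a dense overlapping pseudo-peptic map (lengths 5–20, ~4×
  redundancy). Protection is applied as region-wise factors on construct
  B.

What passing tests do and do not show: the generators share the model
class with the fitters, so recovery tests validate correctness and
statistical efficiency of the estimators, not robustness to real-data
pathologies (baseline curvature, correlated noise, partial-loop
back-exchange variation, mass-transport-limited binding), which are out
of scope.

# Problem sizes

The test suite and acceptance script run fits at the study's native
sizes: 96-point four-curve global unfolding fits (50 replicates in the
recovery studies), 4500-point five-trace kinetic fits, 18-injection
isotherms (50 replicates), 551-point thermal ramps, and ~200-entry
difference maps. The full suite completes in about two minutes on one
CPU.

# Known limitations

* No heat-capacity (Gibbs–Helmholtz) analysis of the thermal
  transitions, four-state models, mass-transport or bivalent binding
  models, multi-site ITC, raw power-trace integration, spectral HDX
  processing, or residue-level exchange deconvolution.
* The LEM fit's $\Delta G_I^0$ precision is bounded by the single-curve
  design noise (see above); comparisons between constructs
  ($\Delta\Delta G$) are more robust than absolute values.
* Which single m-value the source tabulated per construct is not
  determinable; both $m_I$ and $m_D$ are always reported.
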