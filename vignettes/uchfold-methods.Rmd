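---
title: "Models and methods behind uchfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uchfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uchfold)
```

uchfold reimplements, as one tested toolkit, the quantitative analyses used
to characterise the folding of UCH-family deubiquitinases — proteins whose
backbone threads a Gordian knot and whose folding kinetics span six orders
of magnitude. This vignette records the models, their assumptions, the
numerical choices, and the places where the design was genuinely open.
Everything is in one unit system: energies in kcal mol⁻¹, rates in s⁻¹,
denaturant in mol L⁻¹, temperature in kelvin, with `R = 1.9872e-3`
kcal mol⁻¹ K⁻¹ and a default working temperature of 298 K (the stated
experimental temperature; deliberately not 298.15).

## Equilibrium unfolding

A denaturant titration read at many wavelengths is an `m × n` matrix
(wavelengths × titration points). `svd_decompose()` factorises it and
scores every component by the first-order autocorrelation of its
unit-normalised basis spectrum (U column) and coefficient vector (V
column), `C = Σᵢ wᵢ wᵢ₊₁` — the Henry–Hofrichter diagnostic: smooth,
signal-bearing vectors score near 1, white noise near 0.
`count_significant_components()` counts components contiguously from the
first whose U **and** V autocorrelations both exceed the threshold
(default 0.8). Which of U or V the threshold should apply to was an open
choice; requiring both is the conservative reading and is what the pure-
noise null (count 0) and the two-state titration (count 2) are tested
against.

`fit_two_state_equilibrium()` fits the linear extrapolation model:
`ΔG(D) = ΔG_H₂O − m·D`, denatured fraction
`f_D = 1/(1 + exp(ΔG(D)/RT))`, observed signal
`(y_N + s_N D)(1−f_D) + (y_D + s_D D) f_D` with linear baselines per
channel. Baselines enter linearly, so for any (ΔG, m) they are profiled
out by a single multi-right-hand-side least-squares solve (variable
projection); the outer optimisation is a 2-parameter Nelder–Mead from a
grid of starts (midpoint initialised at the concentration of steepest
signal change, m over 1–5 kcal mol⁻¹ M⁻¹), polished by BFGS. Standard
errors come from the numerical Jacobian of the profiled residuals; the
midpoint `[D]₅₀ = ΔG/m` gets a delta-method error. A fit whose midpoint
falls outside the scanned denaturant range, or whose fitted transition
amplitude is indistinguishable from the residual noise, is reported as
non-converged rather than returned. The emission-maximum variant
(`fit_lambda_max()`) uses the same machinery with intercept-only
baselines, since a wavelength-of-maximum has no meaningful baseline slope.

## Stopped-flow kinetics

`fit_multiexponential()` fits `offset + Σ Aᵢ exp(−kᵢ t)` for 1–3 phases;
amplitudes and offset are again linear and profiled out, the rates are
optimised on the log scale from log-spaced multi-starts and polished by
Levenberg–Marquardt. The phase count is the smallest one that the
extra-sum-of-squares F test (`extra_ss_f_test()`, α = 0.05) cannot
improve on; rates closer than 1.5× are merged, a fitted rate at the
sampling bound `1/(2Δt_min)` is an error, and the F-test cascade stops
once the residual is at numerical noise (machine-epsilon residuals make F
meaningless). Points before the instrument dead time — default 2 ms,
typical for stopped-flow mixers, configurable per trace — are discarded,
so fitted amplitudes refer to the first observed instant.

Chevron plots are fitted in `log₁₀(k_obs)` space:
`k_obs(D) = k_f^{H₂O} exp(m_f D/RT) + k_u^{H₂O} exp(m_u D/RT)` with
`m_f < 0 < m_u`. Rates along a chevron span many decades, so log-space
residuals are the only way to weight both arms evenly; errors on rates
are multiplicative, making log residuals approximately homoscedastic.
Arm-wise linear regressions of log k on D give closed-form starting
values. Derived quantities are populated with delta-method errors:
`ΔG = RT ln(k_f/k_u)`, `m_kin = m_u − m_f`, `[D]₅₀ = ΔG/m_kin`. Note that
water-extrapolated unfolding rates are extrapolations over ~8 M of
denaturant: their relative errors are intrinsically large (a recovery
test documents ±0.5 on log₁₀ k_u at 5% rate noise), while ΔG is much
better determined.

## Double-jump analysis

`final_concentration()` tracks denaturant and protein through mixing
sequences (each step mixes the protein-carrying solution with an added
buffer at a volume ratio). `global_fit_shared_rates()` fits all traces of
an interrupted-refolding series with one shared rate set and free
per-trace amplitudes/offsets; the per-phase amplitude versus aging time
is then fitted by `fit_amplitude_buildup()` to
`A(t) = A_∞(1 − exp(−kt))`, with a lag flagged whenever a delayed-onset
(sequential two-step) model wins the F test — a lag too subtle for the
eye is still statistically detectable.

`three_state_relaxation()` builds the 3×3 rate matrix of
A ⇌ B ⇌ C, returns the two non-zero relaxation rates (negated
eigenvalues) and the analytic population time courses (tested against
stiff ODE integration to 1e-8). `fit_linear_three_state()` inverts this:
given the build-up curves of the two folded species it seeks microscopic
rates whose predicted B and C populations reproduce them. One point is
worth recording: with an independent response scale per curve the four
microscopic rates are **not identifiable** — a second, distinct rate set
reproduces both curve shapes exactly (same trace and determinant of the
relaxation spectrum, amplitude ratios absorbed by the scales). The fit
therefore shares a single response scale between the two curves, i.e.
assumes the two folded species contribute equally per molecule to the
unfolding amplitude — the conventional reading of interrupted-refolding
amplitudes — and this restores identifiability. The nested two-state
alternative (one building species, curves identical up to per-curve
scale) is always fitted alongside and preferred when the F test does not
justify the extra rates. Initial populations default to pure denatured
state, configurable.

## Hydrogen–deuterium exchange

Per-residue cross-peak intensities are fitted to `I₀ exp(−kt)` with the
floor fixed at 0 (a fully exchanged peak vanishes; a free floor is
optional). Decays losing less than 5% of their intensity are reported as
below detection with a rate upper bound, and turn into protection-factor
lower bounds. Intrinsic rates use the additive log-factor model on the
poly-DL-alanine reference scale: per-residue acid/base factors of the
residue's own side chain and its left neighbour, N/C-terminal
corrections, `[D⁺]` and `[OD⁻]` from the pD (ion product pK_D = 15.05),
and Arrhenius temperature corrections (activation energies 14/17/19
kcal mol⁻¹ for acid/base/water catalysis) from the 293 K reference. The
reference table ships as a plain-text file
(`inst/extdata/hdx_reference_rates.csv`) with a provenance header; side
chains are taken in their dominant ionisation state near neutral pD. The
protection factor is `PF = k_int/k_obs`; both PF and log₁₀PF are
reported, and PF < 1 is flagged as anomalous rather than silently
accepted. The buffer pD convention (glass-electrode reading + 0.4) is an
argument, not an assumption.

## Thermal denaturation

`gibbs_helmholtz()` implements
`ΔG(T) = ΔH_m(1 − T/T_m) − ΔC_p[(T_m − T) + T ln(T/T_m)]`, and
`fit_thermal_two_state()` wraps it in the same variable-projection
two-state machinery with linear baselines. ΔC_p is **fixed** (default 0)
unless explicitly fitted: a melt spanning ~55 K constrains it poorly, and
fitting it by default merely inflates the T_m error. Normalisation to
fraction folded uses the fitted baselines. `tm_shift()` differences two
fits with propagated errors; a null-shift calibration test keeps the
error estimate honest.

## Binding calorimetry

`one_site_expected_heats()` uses the closed-form single-site quadratic
for the bound complex and idealized perfusion-cell displacement (each
injection dilutes cell contents by `1 − v/V₀` and ejects a matching share
of accumulated complex); it is tested against a mass-balance bisection
oracle at 1e-9. `fit_one_site()` estimates (Ka, ΔH, offset) with the
c-value checked against the fittable window 0.5–1000.
`global_fit_temperature_series()` fits `ΔH(T) = ΔH₀ + ΔC_p(T − T₀)`,
`ΔS(T) = ΔS₀ + ΔC_p ln(T/T₀)` to the per-temperature (Ka, ΔH) pairs,
combining enthalpy residuals with free-energy residuals (`RT ln Ka`), both
in kcal mol⁻¹, so neither observable dominates. The reference
temperature is 298.15 K (standard conditions). Outlier temperatures are
the caller's decision to exclude; no automatic rejection is applied.
Reported `tds = T·ΔS`: in some published tables this row is labelled
−TΔS while carrying the value of +TΔS (ΔH − TΔS reproduces ΔG only with
the positive sign), so the package names the quantity unambiguously.
Entropy units follow the field convention of cal mol⁻¹ K⁻¹ for ΔS with
ΔC_p in kcal mol⁻¹ K⁻¹.

## Contact order

`relative_contact_order()` computes `RCO = (1/(L·N)) Σ |i−j|` over all
heavy-atom pairs within 6 Å with residue separation ≥ 2, each qualifying
atom pair counting once — the original contact-order convention. All
three knobs (cutoff, separation floor, chain) are arguments, because
published RCO values are convention-sensitive; residues are renumbered
1..L after gap compaction and L is the resolved-residue count. PDB/mmCIF
parsing is delegated to bio3d; the implementation is verified against a
brute-force all-pairs scan and is rigid-body invariant by construction.

## The synthetic-data generator

Each `simulate_*()` function emits a dataset in the module's native
container plus the ground-truth record, under a fixed seed (the session
RNG stream is saved and restored, so generators are pure). The defaults
encode the experimental design the analyses expect: 41-point urea
gradients (0–6 M) read at 121 wavelengths built from two Gaussian basis
bands weighted by the two-state population; log-sampled kinetic traces
beginning at the 2 ms dead time; 15 points per chevron arm with
log-normal rate noise; aging times log-spaced from 10 ms to 100 s with
exact three-state propagation; HDX decays sampled over five lifetimes;
four-temperature ITC series (20/25/30/37 °C) at 27.5 µM cell / 275 µM
syringe. Default noise is 1% proportional for spectra and traces, 2% of
the largest heat for ITC, 5% for HDX intensities — instrument-grade
values. Parameter presets for the three paralogs live in
`uchfold_presets()` with provenance strings.

What the generator does **not** emulate: photophysical artifacts,
detector nonlinearity, baseline drift within a single scan, shot noise,
peak overlap in crowded NMR spectra, and aggregation during thermal
scans. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated statistical model, not robustness to every
instrument pathology.

## Problem sizes and runtime choices

The test-suite and acceptance runs use the generator defaults above:
4961-point titration matrices (20 seeds for the equilibrium recovery
study), 30-point chevrons, 8 aging times × 300-point traces, 30 HDX
residues × 12 time points, 111-point melts, and 4 × 19-injection ITC
series. These sizes match the modelled experiments while keeping each
analysis comfortably interactive.

## Known limitations

* Equilibrium analysis is strictly two-state; three-state equilibrium
  models are out of scope (the component-count diagnostic is the guard:
  more than two significant SVD components means the model does not
  apply).
* The three-state kinetic inference assumes equal spectroscopic response
  of the folded species (see above) and a linear scheme; parallel
  pathways are not modelled.
* Intrinsic-rate prediction inherits the accuracy of the reference
  factor table (transcribed to the precision available) and the
  constant-pK_D approximation across temperature; at the 25 °C working
  temperature the Arrhenius correction from 293 K is small.
* Thermal fits assume reversibility; heating/cooling hysteresis is only
  detectable if both scans are supplied.
* RCO values depend on the contact convention; comparisons are only
  meaningful within one convention.
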