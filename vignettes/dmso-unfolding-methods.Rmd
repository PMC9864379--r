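---
title: "Methods: two-state DMSO unfolding, 15N relaxation, and DSC stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state DMSO unfolding, 15N relaxation, and DSC stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsofold)
```

## Scope

`dmsofold` analyses the chemical unfolding of small, disulfide-stabilised
proteins induced by dimethyl sulfoxide (DMSO), followed by two
complementary experiments: NMR peak-volume titrations at constant
temperature, and DSC temperature scans at constant DMSO content.  A third
arm analyses backbone ¹⁵N relaxation to verify that the NMR-visible
(folded) fraction keeps a rigid backbone in the mixed solvent.  Because
raw spectrometer and calorimeter exports are rarely shareable, every
analysis has a seeded synthetic generator producing data with the same
statistical structure, so the whole pipeline is testable end to end
without external files.

## The two-state unfolding model

The folded (F) and unfolded (U) states exchange with free energy

$$\Delta G_{F-U}(c) = \Delta G^0_{F-U} - m\,c,$$

where $c$ is the molar DMSO concentration and $m$ (kJ mol⁻¹ M⁻¹) is the
linear sensitivity of unfolding to the denaturant.  At the midpoint
$c_{50}$ the free energy vanishes, so $\Delta G^0 = m\,c_{50}$.  The
folded fraction is the logistic

$$f_F(c) = \frac{1}{1 + \exp\left(\frac{-\Delta G^0 + m c}{RT}\right)},$$

and the relative volume of a folded-state HSQC cross-peak follows

$$I/I_0 = \frac{a}{1 + \exp\left(\frac{m (c - c_{50})}{RT}\right)} = a f_F(c).$$

`fit_two_state()` estimates $(a, m, c_{50})$ by nonlinear least squares
and reports $\Delta G^0 = m c_{50}$ with an error propagated through the
full $(m, c_{50})$ covariance; the product is never refit.  Initial
guesses come from the data (plateau, half-crossing, central slope).
Defaults: $T = 310$ K, $R = 8.314\times10^{-3}$ kJ mol⁻¹ K⁻¹, unit
weights (the weighting of the original analysis is unknown; a per-point
SD column is accepted).  The amplitude is bounded to $(0, 1.5]$: an
unbounded $a$ trades off against $m$ on truncated transitions.

**Units.** All free energies are kJ mol⁻¹ and $m$ is kJ mol⁻¹ M⁻¹.
Reports of unfolding enthalpies in "kJ/M" in the calorimetry/NMR
literature of this system are read as kJ mol⁻¹; we flag rather than
propagate the ambiguity.

**Concentration axis.** The model is fit in molar units; v/v% inputs are
converted with $c = (vv/100)\,\rho\,1000/M$ using $\rho = 1.10$ g mL⁻¹
and $M = 78.13$ g mol⁻¹ (DMSO at 25 °C), under which 70 v/v% is 9.86 M.
Midpoints are reported on both axes.  Whether the original per-peak fits
used molar or volume units is not recorded; the logistic is monotone in
either, and the molar axis is the one on which the linear free-energy
model is defined.

**Censoring.** Folded-state peaks vanish at high DMSO (around 82 v/v% in
this system).  Points with missing or nonpositive volumes are flagged
censored and excluded from fitting but kept in outputs — they are not
zeros, because the baseline noise floor, not the model, determines them.

**Pooling.** `pool_peaks()` returns the unweighted mean ± sample SD of
$\Delta G^0$ over converged peaks, matching how multi-peak averages are
conventionally quoted for this experiment.

## Viscosity compensation of titration intensities

Adding DMSO raises viscosity several-fold, shortening ¹H T₂ and
suppressing peak volumes independently of unfolding.  Each titration
point is therefore measured twice, with the transverse preparation time
doubled (defaults 5.5 and 11 ms).  Assuming monoexponential decay,
`back_extrapolate_intensity()` recovers the zero-time intensity
$I_0 = \exp(\ln i_1 + t_1 (\ln i_1 - \ln i_2)/(t_2 - t_1))$, which for
$t_2 = 2t_1$ is $i_1^2/i_2$, and an apparent T₂
$(t_2-t_1)/\ln(i_1/i_2)$.  A non-decaying pair ($i_2 \ge i_1$, possible
under noise) is returned as $i_1$ with a warning instead of
extrapolating upward.  `correct_series()` then multiplies by the
solution-volume ratio (dilution of a fixed solute amount), divides by
the per-point pulse-calibration scalar (an instrument-side input we
cannot recompute; default 1), and normalises to the corrected intensity
at the reference condition — the lowest-DMSO point of each series unless
overridden.  The corrected $I/I_0$ is exactly 1 at the reference and is
invariant to the T₂ trajectory.

One consequence of normalisation worth stating: dividing by the
reference intensity cancels the generating amplitude entirely, and the
observable plateau becomes $1/f(c_{\mathrm{ref}})$, marginally above 1.
Recovery tests compare the fitted $a$ against that value, not the
generator's nominal $a$.

## ¹⁵N relaxation analysis

Spectral densities use the model-free form
$J(\omega) = \tfrac{2}{5}\left[S^2\tau_c/(1+(\omega\tau_c)^2) +
(1-S^2)\tau/(1+(\omega\tau)^2)\right]$.  The fitted model ("M2":
spherical tumbling, one global $\tau_c$, per-residue $S^2$, no internal
correlation time) omits the second term; $\tau_e$ is accepted by the
forward model but off by default.  Dipolar and CSA constants are
recomputed from first principles at the requested field with
$r_{NH} = 1.02$ Å and $\Delta\sigma = -160$ ppm — field-standard values,
configurable, not derivable from the data themselves.  The ¹⁵N
gyromagnetic ratio is negative, and the rate expressions use signed
frequencies; this is what makes the reduced-mapping convention below
self-consistent.

`fit_model_free()` proceeds in three stages: (1) $\tau_c$ from numerical
inversion of the rigid-limit R₂/R₁ ratio (for the M2 model this ratio is
independent of $S^2$, so the estimator is unbiased even for mobile
residues, though we still filter NOE < 0.65 and R₂ outliers beyond 1.5
SD of the 10% trimmed mean to guard against exchange and fast internal
motion); (2) per-residue $S^2$ by weighted least squares on (R₁, R₂,
NOE); (3) refinement of the global $\tau_c$ minimising the total
χ².  Errors come from seeded Monte-Carlo resampling of the rates within
their stated errors (default 200 replicates); replicates re-estimate
$\tau_c$ via the R₂/R₁ inversion rather than repeating stage 3, which
changes $\tau_c$ by under 0.3% in the tested regimes at a fraction of
the cost.  Zero stated errors are floored at a small fraction of each
observable so noiseless data remain well conditioned; $S^2$ estimates
are invariant to uniform error scaling.

`reduced_jmap()` inverts the rates algebraically into $J(0)$,
$J(\omega_N)$ and $J(0.87\omega_H)$, approximating all proton-band terms
by a single sampling frequency.  Round-trip tests against the forward
model bound the approximation error below 2% (measured < 1%) for
$S^2 \ge 0.5$, $\tau_c \in [2, 15]$ ns at both 50.684 and 70.966 MHz.
A negative mapped $J(0)$ is returned but flagged unphysical.

`exchange_screen_r1r2()` flags residues whose R₁·R₂ product exceeds the
10% trimmed mean by more than 1.5 sample SDs.  This is a *screen*, not a
hypothesis test: with a 1.5σ cut, Gaussian measurement noise alone flags
roughly 7% of residues by chance.  The tested contract (an injected
Rex = 5 s⁻¹ flagged, nothing else) therefore uses low-noise uniform
synthetics; on real data the screen is a shortlist generator, mirroring
how the product plot is used in practice (a negative finding means no
residue stands far above the band).

## DSC melting points and the stability parabola

`excess_heat_capacity()` subtracts an optional reference trace and a
linear chord baseline anchored on the means of pre- and post-transition
windows (defaults: first and last 5 °C of the scan), warning if a window
overlaps the apparent peak.  A spline baseline was considered and
rejected: the instrument software that produced the published baselines
is unspecified, and a chord is the only reproducible choice.

`extract_tm()` defines $T_m$ as the temperature of maximal excess heat
capacity — the only definition available for irreversible scans, where
equilibrium van't Hoff fitting of the peak would not be meaningful (and
is deliberately omitted).  The grid maximum is refined by a quadratic
fit over ±5 grid points; the reported error combines the fit curvature
with a grid-spacing floor.  On a 0.1 °C grid the refinement lands within
0.01 °C of a symmetric peak's true centre; that 0.01 °C, not machine
precision, is the accuracy contract of the whole thermogram chain.

`fit_tm_parabola()` fits $T_m(x) = p_1 x^2 + p_2 x + p_3$ by OLS in
v/v% units and reports coefficient SEs and $R^2$.  On exact inputs the
coefficients are recovered to numerical precision (tested at 1e-9);
through the full simulate → extract → fit chain the attainable accuracy
is the 0.01 °C extraction contract propagated through the OLS design
matrix, and tests assert exactly that bound.

## Synthetic data: the stated world

The generators encode one fixed scenario each, chosen to match the
experiment they emulate; they are not tuned per test.

* **Titration** (`simulate_titration()`): 12 points spanning 0–88 v/v%
  at 310 K; $a = 1$, $m = 2.3$ kJ mol⁻¹ M⁻¹, $c_{50} = 10$ M (≈71 v/v%,
  so $\Delta G^0 = 23$ kJ mol⁻¹); solution volume growing 350 → 990 µL;
  T₂ shrinking threefold (40 → 13 ms) across the titration as a
  viscosity proxy — only the observable (T₂) is modelled, no
  Stokes–Einstein fit; 2% multiplicative Gaussian noise.  Noise is
  shared by the two delay spectra of a point (they see the same sample);
  an independent per-delay component exists but defaults to 0, because
  dual-delay extrapolation amplifies independent noise by √5, which the
  round-trip accuracy contract (corrected RMS ≤ 1.5× noise SD) excludes.
  Even so, the reference point's own noise propagates into every
  normalised intensity, so the per-seed RMS fluctuates around √2× the
  noise SD; the contract is asserted on the median over seeds.
* **Relaxation** (`simulate_relaxation()`): 53 amide probes (residues
  2–55 minus the proline at 29 of a 55-residue protein), $S^2 \sim
  N(0.87, 0.06)$ clipped to [0, 1], $\tau_c = 7.7$ ns at 70.966 MHz (the
  310 K mixed-solvent regime; 12 ns at 50.684 MHz reproduces the slower
  298 K regime), 2% fractional noise, optional per-residue Rex.
* **DSC** (`simulate_dsc()`): one trace per condition at 0–55 v/v% in
  5% steps, 40–130 °C at 0.1 °C; $T_m$ follows the stability parabola
  (defaults: $p_1 = -2.98\times10^{-3}$, $p_2 = -59.0\times10^{-3}$,
  $p_3 = 93.2$); optional 0.8 °C $T_m$ jitter emulates run-to-run
  scatter.  The endotherm is the equilibrium two-state excess heat
  capacity $C_p^{ex} = \Delta H_{vH}^2/(R T_m^2)\cdot K/(1+K)^2$ with
  $K = \exp(-\Delta H_{vH}/R\,(1/T - 1/T_m))$.  Two deliberate choices:
  the prefactor is evaluated at $T_m$ rather than $T$, so the maximum
  falls *exactly* at $T_m$ (with a $T$-dependent prefactor it shifts
  ~0.1–0.15 °C below, which would contaminate every extraction test with
  a shape artefact); and $\Delta H_{vH} = 600$ kJ mol⁻¹, the round value
  at which the peak's exponential tails drop below 10⁻⁶ of its height
  inside the baseline anchor windows, as the chord-recovery contract
  requires, while keeping a plausible sharp (~7 °C half-width)
  cooperative endotherm.  The real scans are irreversible and the
  equilibrium shape is knowingly wrong for them — immaterial here, since
  only the peak position is ever extracted from these traces.

What a green test does **not** establish: the generators produce
exchange-free, mono-exponentially decaying, single-transition data with
Gaussian noise.  Slow conformational exchange, solvent-exchange line
broadening, scan-rate-dependent (kinetic) $T_m$ shifts, and multi-state
unfolding are all outside the stated world, so passing tests say nothing
about robustness to them.

A note on $R^2$: with 0.8 °C $T_m$ scatter at 12 conditions, the
expected $R^2$ of the parabola fit is
$1 - 9\sigma^2/\mathrm{SS_{tot}} \approx 0.97$, not 0.99; a printed 0.99
implies scatter below 0.8 °C.  The acceptance test asserts the simulated
$R^2$ against this analytic expectation (±3 sampling SDs), which the
0.99 figure also falls inside.

## Reproducibility and numerical choices

* Every stochastic function takes a seed and restores the caller's RNG
  state; identical spec + seed gives bit-identical outputs.
* Config files are JSON (`read_run_config()`); unknown keys are hard
  errors, never silent defaults.  Temperatures are kelvin internally;
  DSC I/O stays in °C with explicit conversion at the boundary.
* Fit non-convergence is a flagged state, not an exception: flat
  titrations (spread < 10% of level) and midpoints outside the sampled
  range are reported `converged = FALSE` with a reason.
* NOE restraint ranges use the standard convention (intra 0, sequential
  1, medium 2–4, long ≥ 5 in $|i-j|$); the cutoffs behind published
  percentages for this system are unstated, so exact reproduction of
  those fractions is not claimed.
* Chemical-shift trajectories are reported, not interpreted: assigning
  fast/slow exchange regimes from drift patterns is qualitative and out
  of scope.

## Limitations

No anisotropic diffusion tensors, multi-field global fits, model
selection across the model-free hierarchy, three-state unfolding,
kinetic (Lumry–Eyring) DSC modelling, or vendor binary formats.  DSC
rescans are not modelled; each scan is analysed independently.
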