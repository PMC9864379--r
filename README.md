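# dmsofold

Two-state analysis of DMSO-induced protein unfolding from NMR and DSC
data.

Small disulfide-stabilised antifungal proteins (55-residue β-barrels of
the PAF family and their variants) keep highly stable folds in water,
yet unfold reversibly when dimethyl sulfoxide is titrated in.  Probing
that equilibrium quantitatively takes three coupled analyses, and this
package implements all of them for people running such titrations:

1. **HSQC peak-volume titrations.**  The folded fraction is read from
   folded-state cross-peak volumes, but rising viscosity shortens ¹H T₂
   and suppresses volumes on its own.  Each point is measured at two
   transverse delays (5.5/11 ms) and back-extrapolated to zero time
   (`I0 = i1²/i2` for doubled delay), then corrected for dilution and
   pulse calibration and normalised (`correct_series()`).  The corrected
   ratios are fit to the two-state model

   ```
   ΔG(c)  = ΔG⁰ − m·c          ΔG⁰ = m·c50
   I/I0   = a / (1 + exp(m (c − c50) / RT))
   ```

   giving the m-value (kJ·mol⁻¹·M⁻¹), the unfolding midpoint `c50`
   (mol/L) and `ΔG⁰ = m·c50` (kJ/mol) per peak, with pooled statistics
   over peaks (`fit_two_state()`, `pool_peaks()`).

2. **Backbone ¹⁵N relaxation** of the NMR-visible fraction: forward
   R₁/R₂/NOE rates from Lipari–Szabo spectral densities, a
   one-global-τc / per-residue-S² model-free fit (`fit_model_free()`),
   reduced spectral density mapping into J(0), J(ωN), J(0.87ωH)
   (`reduced_jmap()`), and R₁·R₂ chemical-exchange screening
   (`exchange_screen_r1r2()`).

3. **DSC stability curves**: reference/baseline subtraction, melting
   points as the excess-heat-capacity maximum (`extract_tm()`), and the
   parabolic stability fit `Tm(x) = p1·x² + p2·x + p3` over DMSO
   content (`fit_tm_parabola()`, `predict_tm()`).

Seeded generators (`simulate_titration()`, `simulate_relaxation()`,
`simulate_dsc()`) emulate all three data types with embedded ground
truth, so every analysis is testable without instrument exports.

## Worked example

```r
library(dmsofold)

# --- titration: simulate, correct, fit --------------------------------
tab  <- simulate_titration(noise_sd = 0.02, seed = 42)  # 6 peaks, 12 points
corr <- correct_series(tab)
fits <- fit_all_peaks(corr, temperature_K = 310)
fits[["C7"]]
#> Two-state unfolding fit, peak C7 (12 points, converged)
#>   a    = 0.9814 +- 0.0057
#>   m    = 2.334 +- 0.082 kJ/mol/M
#>   d50  = 10.030 +- 0.043 M (71.2 v/v%)
#>   dG0  = 23.41 +- 0.85 kJ/mol at 310 K
pool_peaks(fits)
#> Pooled unfolding free energy over 6 peak(s): 23.5 +- 0.3 kJ/mol
```

The generator's truth was m = 2.3, c50 = 10 M (ΔG⁰ = 23 kJ/mol at
310 K, midpoint ≈ 71 v/v%): the fit recovers it within the quoted
errors despite a threefold T₂ collapse and a 350 → 990 µL dilution
across the titration.

```r
# --- relaxation: model-free fit on the 310 K regime -------------------
ds <- simulate_relaxation(noise_sd = 0.02, seed = 42)   # tau_c 7.7 ns, S2 ~ 0.87
fit_model_free(ds, mc_reps = 50, seed = 42)
#> Model-free fit (M2, isotropic): 53 residues at 70.966 MHz
#>   tau_c = 7.67 +- 0.02 ns; mean S2 = 0.868 (range 0.696-1.000)

# --- DSC: melting points and the stability parabola -------------------
tgs   <- simulate_dsc(tm_jitter_sd = 0.8, seed = 42)    # 12 conditions, 0-55%
melts <- lapply(tgs, function(tg) extract_tm(excess_heat_capacity(tg)))
pf <- fit_tm_parabola(data.frame(
  dmso_vv_percent = attr(tgs, "truth")$dmso_vv_percent,
  tm_C = sapply(melts, `[[`, "tm_C")))
pf
#> Tm(x) = -0.002047 x^2 + -0.09298 x + 93.76  (n = 12, R^2 = 0.974)
predict_tm(pf, 50)
#> [1] 83.98897
```

(in °C; the generating parabola gives 82.8 — the 0.8 °C per-point Tm
jitter of this run moves the extrapolated value by about 1 °C).

A published stability curve can be evaluated directly from its
coefficients:

```r
predict_tm(list(p1 = -2.98e-3, p2 = -59.0e-3, p3 = 93.2), c(0, 50))
#> [1] 93.2 82.8
```

## Command line

Every stage is also a subcommand of the `inst/exec/dmsofold` script
(`simulate`, `correct`, `fit-unfold`, `relax-jmap`, `relax-modelfree`,
`dsc-fit`, `report`), configured with `--config config.json` and
emitting CSV tables plus JSON summaries.

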