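# nlsbind

Quantitative biophysics of nuclear localization signal (NLS) peptides
binding importin α, as a tidy R package.

Short NLS patches in cargo proteins (here: candidate NLS regions of the
human peptidyl-arginine deiminases PADI1, PADI2 and PADI3) are recognized
by importin α3 (Impα3) and its IBB-truncated form (ΔImpα3). `nlsbind`
implements the full analysis chain used to characterize such peptides and
their binding, with seeded synthetic-data generators standing in for
instrument raw data so every fitting stage is testable end to end:

* **Peptide physicochemistry** — annotated-sequence parsing with
  intact-protein numbering, capped average masses (N-acetyl +42.04 Da,
  C-amide −0.98 Da), Trp/Tyr extinction coefficients, Beer–Lambert
  quantification, aromatic inventories.
* **Hydrodynamics** — Stejskal–Tanner PFG decay fits
  `I = I₀ exp(−D(γgδ)²(Δ−δ/3))`, Rh from the dioxane internal reference
  (`Rh = 2.12 Å · D_ref/D`), and the random-coil scaling law
  `Rh(nm) = 0.027·MW^0.50`.
* **NMR disorder** — sequence-corrected Hα conformational shifts with a
  swappable random-coil reference table, the inclusive |Δδ| ≤ 0.1 ppm
  coil criterion, and NOE connectivity-range summaries.
* **Fluorescence** — inner-filter correction, addition-spectrum
  comparison, and the quadratic ligand-depletion isotherm
  `F = F₀ + (ΔF_max/2P_T)[(P_T+L_T+K_d) − √((P_T+L_T+K_d)² − 4P_T L_T)]`.
* **ITC** — the single-site injection model (overflow dilution,
  quadratic mass balance with stoichiometry factor n, per-injection
  normalized heats), Kd = 1/Ka, and the thermodynamic profile
  ΔG = −RT ln Ka, −TΔS = ΔG − ΔH.
* **BLI** — drift-corrected association/dissociation fits
  `R = R_eq(1−e^(−k_obs(t−t₀))) − R′(t−t₀)` and
  `R = R₁e^(−k_off(t−t₀)) − R″(t−t₀)`, the pseudo-first-order line
  `k_obs = k_on·c + k_off`, and Kd = k_off/k_on with propagated errors.

Everything is tibble-in/tibble-out with broom-style `tidy()`/`glance()`
methods and ggplot2 `autoplot()` methods for each result type.

## Worked example

Simulate a calorimetric titration at a published preset (ΔImpα3 /
PADI3-NLS1: Ka = 8.0×10⁵ M⁻¹, ΔH = 16.7 kcal/mol, n = 0.82) with
realistic 0.3 kcal/mol injection noise, and refit it:

```r
library(nlsbind)

iso <- simulate_itc(itc_protocol(), ka = 8.0e5, dh = 16.7, n = 0.82,
                    qd = 0.3, sigma = 0.3, seed = 42)
fit <- fit_isotherm(iso, itc_protocol())
fit
#> Single-site ITC fit (19 injections, T = 298.15 K)
#>   Ka = 5.4e+05 +/- 1.1e+05 M-1   (Kd = 1.85 uM)
#>   dH = 19.2 +/- 1.3 kcal/mol   n = 0.892 +/- 0.028   Qd = -0.795
#>   dG = -7.82, -TdS = -27 kcal/mol (entropically driven)
```

The fitted Kd (1.85 μM) sits within the ~30% run-to-run scatter expected
at this noise level around the generating 1.25 μM; the positive ΔH with a
larger favorable entropic term reproduces the entropically driven
signature of these complexes. BLI kinetics from four noisy sensorgrams
(1–10 μM peptide):

```r
sg <- simulate_bli(kon = 0.039, koff = 0.09, sigma = 0.01, seed = 42)
fit_kinetics(sg)
#> BLI kinetic analysis (two-state assumption)
#>   kon  = 0.0382 +/- 0.00022 uM-1 s-1
#>   koff = 0.0923 +/- 0.0013 s-1 (per-trace dissociation mean 0.0896)
#>   Kd   = koff/kon = 2.41 +/- 0.036 uM
```

i.e. kon and koff are recovered within ~2–3% and Kd = koff/kon ≈ 2.4 μM
(generator: 0.09/0.039 = 2.31 μM). Peptide-level properties:

```r
peps <- peptide_properties(parse_annotated_sequence(padi_peptide_presets()$entry))
dplyr::select(peps, name, mass_da, epsilon_280)
#>   name       mass_da epsilon_280
#> 1 PADI1-NLS1   3681.        5500
#> 2 PADI2-NLS2   3455.        1490
#> 3 PADI3-NLS1   3011.        1490
#> 4 PADI3-NLS2   3539.           0
```

(PADI3-NLS2 has no Trp/Tyr and is quantified via Phe at 258 nm; the
PADI1-NLS1 mass is that of the synthesized Cys546Ser sequence.)

`run_pipeline(seed = 1)` chains all stages on synthetic data at the
published presets and renders report tables with 2-significant-figure
rounding and "-" for unfittable cells.

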