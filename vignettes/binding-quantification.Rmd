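---
title: "Quantifying NLS-peptide/importin binding: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NLS-peptide/importin binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlsbind)
library(dplyr)
```

## The scientific problem

Peptidyl-arginine deiminases (PADI1-4, 6) are cytoplasmic enzymes, yet
several isoforms act on nuclear substrates (histone citrullination), which
requires passage through the nuclear pore. The classical route is
recognition of a short nuclear localization signal (NLS) in the cargo by
importin α. `nlsbind` implements the quantitative workflow used to
characterize candidate NLS peptides from PADI1, PADI2 and PADI3 and their
binding to importin α3 (Impα3) and its IBB-domain-truncated form (ΔImpα3):

1. **Peptide physicochemistry** — capped average masses, aromatic
   inventories, extinction-coefficient-based quantification.
2. **Hydrodynamics** — translational diffusion from pulsed-field-gradient
   (PFG/DOSY) decays, hydrodynamic radii via a dioxane internal reference
   and via the random-coil scaling law, and a monomeric/disordered
   consistency verdict.
3. **NMR disorder classification** — sequence-corrected Hα conformational
   shifts against the |Δδ| ≤ 0.1 ppm random-coil band, and NOE
   connectivity-range summaries.
4. **Three independent binding models** — the quadratic ligand-depletion
   fluorescence isotherm, the single-site ITC injection model, and
   drift-corrected biolayer interferometry (BLI) kinetics with
   pseudo-first-order analysis.

No instrument raw data are deposited for this system, so the package ships
seeded generators (`simulate_*`) that emit every instrument-level input
from the stated forward models plus Gaussian noise. Every fitting stage is
therefore testable end to end, and all recovery claims in the test suite
are claims about those generators — see "What the simulations do and do not
show" below.

## Peptide physicochemistry

Masses are sums of standard *average* residue masses plus one water, with
cap deltas of +42.04 Da (N-acetyl) and −0.98 Da (C-amide). Synthetic NLS
peptides are capped at both termini to avoid charge artifacts and fraying.
Cysteine contributes its reduced mass; the peptides under study were
deliberately Cys→Ser mutated to avoid disulfides, so no cystine correction
is offered.

```{r masses}
peps <- parse_annotated_sequence(padi_peptide_presets()$entry)
average_mass(peps)
```

Note a documented discrepancy: the published mass table lists 3697.16 Da
for PADI1-NLS1, which matches the wild-type Cys-containing span, while the
synthesized peptide carries Cys546Ser and computes to 3681.15 Da (exactly
the 16.06 Da S→C difference). The package always reports the mass of the
sequence as given.

Quantification coefficients are additive per residue: 5500 (Trp) and
1490 (Tyr) M⁻¹cm⁻¹ at 280 nm. For peptides with no Trp/Tyr the package
warns and points to phenylalanine absorbance at 258 nm; the per-Phe
coefficient there is a configurable default of 200 M⁻¹cm⁻¹ (the
literature method the study cites prints no single value; any replacement
can be supplied through `extinction_model()`).

## Hydrodynamics

PFG decays are fit to the Stejskal–Tanner mono-exponential

$$I(g) = I_0 \exp\!\big(-D\,(\gamma g \delta)^2 (\Delta - \delta/3)\big),$$

which is the standard form for this experiment (the study does not print
its fitting equation; this choice is recorded here as the package's own).
Defaults: γ = 26752 rad s⁻¹ G⁻¹ (¹H), δ = 4 ms, Δ = 100 ms, gradients
2–45 G cm⁻¹ — a grid over which a ~1 kDa–4 kDa peptide decays by one to
two e-folds. Starting values come from a log-linear regression; the
nonlinear refinement supplies σ(D) from the covariance matrix.

Two independent radius estimates are produced:

* **Reference route**: with 1% dioxane co-dissolved (Rh = 2.12 Å),
  temperature and viscosity cancel in the Stokes–Einstein ratio,
  Rh = 2.12 · D(dioxane)/D(peptide). The measured dioxane D is fit from
  its own decay in the same dataset; the simulator always emits the paired
  trace. Its default reference D (6.141×10⁻⁶ cm² s⁻¹) reproduces the
  D-ratio of ~6.6 observed for these peptides. Because the study does not
  print its measured dioxane D, reference-route radii are consistency
  checks, never fit targets.
* **Scaling-law route**: Rh(nm) = (0.027 ± 0.01)·MW^(0.50 ± 0.01) for
  random-coil polypeptides. First-order propagation of the printed
  coefficient uncertainties yields ±≈6 Å at these masses — larger than the
  ±2 Å quoted alongside the published radii, whose provenance is not
  reproducible from the printed inputs; the central values agree.

`assess_monomeric_disordered()` declares a peptide consistent with a
monomeric random coil when the two radii agree within the sum of their
uncertainties.

## Disorder classification

Observed Hα shifts are compared with a random-coil reference corrected for
neighboring-residue effects. The reference table ships as plain CSV data
(`inst/extdata/`), keyed by residue and atom, with a +0.29 ppm correction
for residues preceding proline; any alternative coil scale with the same
columns can be swapped in. A peptide is classified *random-coil* when
every unambiguously assigned residue satisfies |Δδ| ≤ 0.1 ppm — the
threshold is inclusive at the boundary and evaluated strictly over all
residues (no outlier allowance; an isolated-outlier variant would be easy
to add but is deliberately not the default). Residues lacking a reference
entry are excluded with a warning rather than guessed.

NOE contacts are summarized by sequence separation: sequential (j−i = 1),
medium (2–4), long (>4). A contact set is coil-consistent only when
sequential contacts exist and medium/long counts are zero; an empty set is
indeterminate, not coil-consistent.

## Fluorescence: the ligand-depletion isotherm

At the study's design — receptor fixed at 3 μM, peptide titrated over
0–30 μM, Kd of order 1–30 μM — the bound peptide is a large fraction of
total, so the hyperbolic isotherm is invalid and the quadratic
mass-balance root must be used:

$$F = F_0 + \frac{\Delta F_{max}}{2 P_T}\Big[(P_T + L_T + K_d) -
 \sqrt{(P_T + L_T + K_d)^2 - 4 P_T L_T}\Big].$$

Numerical notes: the discriminant is algebraically ≥ Kd² but is clipped at
zero against floating-point rounding; ΔFmax is unconstrained in sign (the
signal *decreases* on binding in this system); residuals are unweighted by
default (no weighting scheme is stated for the original fits), with
per-point weights available. The fit flags Kd values outside the window
(P_T/10, 10·max L_T) as unidentifiable — a documented convention, not a
published rule — mirroring the titrations for which no trustworthy Kd
could be obtained. The convergence of the depletion model to the
hyperbola is first order in P_T/K_d (max deviation 0.148·P_T/K_d of the
saturation amplitude, at L_T = K_d/2), which is why quantitative
"hyperbolic-limit" checks in the tests are run deep in the limit
(P_T = K_d/10⁵).

Inner-filter attenuation uses the standard half-absorbance correction
F·10^((A_ex+A_em)/2); the original work cites the correction without
printing a formula.

## ITC: the single-site injection model

Overflow-cell dilution after injection j (volumes v_k, cell volume V₀):

$$L_{T,j} = [L]_{syr}\Big(1-\prod_{k\le j}(1-v_k/V_0)\Big),\qquad
  P_{T,j} = [P]_{cell}\prod_{k\le j}(1-v_k/V_0),$$

with the apparent stoichiometry n scaling the binding-competent protein.
The complex concentration is the quadratic root of the 1:1 mass balance
(Ka in M⁻¹; concentrations handled internally in molar, exposed in μM),
and the ligand-normalized heat of injection j is

$$Q_j = \frac{V_0\,\Delta H}{v_j [L]_{syr}}
 \big([PL]_j - [PL]_{j-1}(1 - v_j/V_0)\big) + Q_d .$$

V₀ defaults to 200.3 μL (the nominal cell volume of the instrument class
used; configurable — all printed-value reproductions are V₀-independent).
The default protocol is 19 × 2 μL injections of 100 μM peptide into 10 μM
protein at 298.15 K, reaching molar ratio ≈ 2.1. Fits run over
(log₁₀Ka, ΔH, n, Q_d) with data-derived starts (tail → Q_d, first
injection → ΔH, isotherm midpoint → n). Derived quantities:
Kd = 10⁶/Ka μM, ΔG = −RT ln Ka (R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹),
−TΔS = ΔG − ΔH, and the binding is labeled *entropically driven* when
ΔH > 0 and −TΔS < 0 — the signature observed for all these pairs.

The closed-form pipeline is verified in the tests against an independent
iterative equilibrium solver (root-finding on the mass balance,
re-equilibrated per injection) to < 10⁻⁸ kcal mol⁻¹ over 1000 random
parameter draws. A synthetic thermogram layer (exponential power peaks,
trapezoidal re-integration over half-open injection windows) closes the
loop from power traces back to isotherms within 0.1%.

**A caution on precision at c ≈ 1.** For the Impα3 presets the Wiseman
parameter c = n·Ka·[P] is 0.6–1.3. In this regime Kd is intrinsically
ill-determined: at a realistic per-injection noise of 0.3 kcal mol⁻¹ the
median relative Kd error across seeded refits is ≈ 35% pooled over all
presets (≈ 48% at c ≈ 0.85 alone), even though the estimator is
median-unbiased and recovers all four parameters to ~10⁻¹² on noiseless
data. This is an information limit of the experiment design, not of the
optimizer, and it is consistent with the ~30% between-run repeatability
reported for the original measurements.

## BLI: drift-corrected two-state kinetics

The default schedule is 30 s baseline, 120 s load, 30 s baseline, 120 s
association (t₀ = 180 s), 120 s dissociation (t₀ = 300 s). Association and
dissociation segments are fit separately:

$$R(t) = R_{eq} - R_{eq}e^{-k_{obs}(t-t_0)} - R'_{eq}(t-t_0), \qquad
  R(t) = R_1 e^{-k_{off}(t-t_0)} - R''_{eq}(t-t_0),$$

with independent signed linear drift per segment. Both forms carry
structural identities — R(t₀) = 0 for association, R(t₀) = R₁ for
dissociation — asserted for arbitrary parameters in the tests. Observed
rates at concentrations 1–10 μM feed the pseudo-first-order regression
k_obs = k_on·c + k_off (ordinary least squares; c in μM so k_on is natively
μM⁻¹ s⁻¹), and Kd = k_off/k_on with first-order quadrature error
propagation. A negative fitted intercept is reported as-is with a warning
and floored at zero only in the derived Kd. Every result records the
two-state assumption under which Kd = k_off/k_on is valid.

Simulator conventions (not stated by the original study): the equilibrium
response is the 1:1 Langmuir R_eq = R_max·c/(c + Kd); traces are
reference-subtracted, the load segment rises exponentially, and the second
baseline ramps linearly back to zero at the association start so that
simulated traces are continuous at every segment boundary while preserving
R(t₀) = 0 exactly.

## What the simulations do and do not show

The generators reproduce: the exact forward models above at σ = 0 (tested
pointwise), homoscedastic Gaussian noise, per-segment linear drift in BLI,
paired internal-reference DOSY traces, and coil/helical-segment shift
tables drawn around the packaged reference scale. They do **not** emulate
instrument-specific artifacts (buffer-mismatch peaks, biosensor depletion,
spectral overlap, baseline curvature), slow-kinetics heat loss in ITC, or
assignment ambiguity in NMR. Recovery results on synthetic data therefore
bound what the models can do under ideal noise, not what any instrument
will deliver; the published experimentally fitted constants are carried
only as presets and arithmetic consequences, never re-derived from raw
data (none are deposited).

Problem sizes used throughout the test suite and the report pipeline —
16-point titrations, 19-injection isotherms, 0.2 s-sampled sensorgrams at
four concentrations, 16-point gradient decays, 13–20 seeded replicates per
recovery study — match the study designs while keeping a full run in
about a minute.

## Reproducible pipeline

`run_pipeline(seed)` executes every stage on synthetic data at the
published presets and renders tables mirroring the published layout, with
2-significant-figure rounding and "-" for cells where a fit failed or was
never obtainable (failed fits never fabricate numbers). Reruns with the
same seed are byte-identical; `write_report()` adds TSV/JSON artifacts and
a log with the seed and package version.

```{r pipeline}
report <- run_pipeline(seed = 1)
render_report_table(report)$bli
```

## Known limitations

* Single-site 1:1 models only: no multi-site, competitive or multi-state
  kinetic schemes (Kd = k_off/k_on is reported under the recorded
  two-state assumption).
* No NLS prediction, docking, spectral processing or resonance assignment;
  NOE intensities enter as pre-classified labels.
* The random-coil scale and its neighbor corrections are as shipped;
  temperature/pH re-referencing beyond the packaged table is out of scope
  (metadata is provenance only).
* The quoted uncertainties of the published radii and kinetic Kd values
  cannot be reproduced from any simple propagation of the printed inputs;
  the package documents and uses first-order quadrature throughout.
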