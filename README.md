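# sonocryst

Analysis toolkit for **ultrasound-assisted anti-solvent crystallization
of oiling-out systems** — systems in which adding a miscible poor
solvent drives the solute into oil-like droplets (liquid–liquid phase
separation) instead of nucleating crystals. The running example is
trisodium fructose 1,6-diphosphate (FDPNa₃, C₆H₁₄O₁₂P₂, 340.12 g/mol)
crystallized from water by ethanol addition, with and without a 100 W
ultrasound bath.

The package is aimed at crystallization researchers who have (a)
induction-time tables versus supersaturation, (b) two-phase composition
measurements, and/or (c) molecular-dynamics-style outputs (energy
tables, coordinate frames) from field-driven simulations, and want a
tested, reproducible path from those inputs to nucleation parameters,
balance audits and demixing statistics.

## What it computes

**Nucleation kinetics.** Classical nucleation theory predicts
`ln t_ind = A + B/(ln S)²` with `B = 16πγ³v²/(3k³T³)`. Oiling-out
systems show two slopes — one per supersaturation regime — so the
package fits a two-branch changepoint regression (automatic RSS-minimal
split or an explicit threshold) and converts each slope into the
interfacial energy `γ = (3Bk³T³/16πv²)^{1/3}`, critical radius
`r_c = 2γv/(kT ln S)`, molar barrier
`ΔG_c = 16πγ³v²/(3(kT ln S)²)·N_A` and critical nucleus size
`N_c = (4π/3)r_c³/v`. The published induction-time tables for FDPNa₃
(100 W ultrasound and silent) ship as fixtures with their printed CNT
columns for cross-checking.

**Phase equilibrium.** Ternary (water/ethanol/solute) compositions,
per-component mass-balance audits of measured two-phase splits, the
lever rule with consistency flagging, relative supersaturation
`σ = (C − C*)/C*`, solubility lookups, and strictly interpolated
(never extrapolated) oiling-out/nucleation boundary curves.

**Pulsed-field surrogate.** The Gaussian-enveloped sinusoid
`E(t) = E₀ exp(−(t−t₀)²/2σ_t²) cos(ω(t−t₀))` used as an MD stand-in
for ultrasound: evaluation, sampling, closed-form-validated fluence,
and bit-exact field tables for MD-engine input.

**MD post-processing.** XVG-dialect energy tables and GRO frames in;
pair interaction energies (Coul-SR + LJ-SR) with steady-state tail
means, axis density profiles with exact count conservation, a
total-variation demixing index, single-linkage cutoff clustering under
periodic boundaries, and an onset detector for particle-count traces.

**Synthetic data.** Seeded generators for every input above, including
a toy Brownian-dynamics simulator (300 soft-core particles, periodic
5×5×5 nm box) whose oiled-out solute droplet melts progressively under
increasing pulsed-field amplitude — the desk-scale analogue of
ultrasound alleviating solute clustering.

## Worked example

```r
library(sonocryst)

mol <- molecular_params(formula = c(C = 6, H = 14, O = 12, P = 2),
                        density = 1.6)  # v = MW/(rho N_A)
tab <- cnt_table(induction_table("ultrasound"), mol,
                 split = 2.05, units = "paper")
print(attr(tab, "fit"))
#> Two-branch CNT fit (split at S = 2.05)
#> low-S branch:  CNT branch fit: ln t = 8.7975 + 0.3752 / (ln S)^2   [S in 1.8..2, n = 4, RSS = 0.00254]
#>   interfacial energy: 2.3230 mJ/m^2
#> high-S branch: CNT branch fit: ln t = 7.8331 + 0.8906 / (ln S)^2   [S in 2.1..2.3, n = 3, RSS = 0.000699]
#>   interfacial energy: 3.0988 mJ/m^2
head(tab, 3)
#>      S t_ind_s ln_t_ind branch gamma_mJ_m2   N_c dG_c_J_mol r_c_nm
#> 1 1.80   19800    9.893    low       2.323 3.695       2692 0.6778
#> 2 1.90   15840    9.670    low       2.323 2.838       2258 0.6207
#> 3 1.95   15840    9.670    low       2.323 2.519       2086 0.5966
```

Reading: the ultrasound-treated data split into two regimes at
S ≈ 2.05; the high-supersaturation branch has the steeper slope
(B = 0.89 vs 0.38) and hence the larger effective interfacial energy.
The γ, ΔG_c and r_c columns depend on the assumed molecular volume
(here from an assumed 1.6 g/cm³ density) — supply the measured density
or volume to reproduce a specific study's absolute values. The
`ln_t_ind` column and the barrier↔radius identity
(`radius_from_barrier(5.552e-3, 2743.888)` → 0.44 nm) reproduce the
published table arithmetic exactly.

Field-driven demixing, one run:

```r
res <- toy_simulate(demixing_spec(amplitude = 15, seed = 11))
last <- res$trajectory[[length(res$trajectory)]]
demixing_index(density_profile(last, "x", 10), "solute", "ethanol")
#> [1] 0.2611111
pair_energy(res$energies, "solute-solute")$tail_mean
#> [1] -119.6
```

The same seed with `amplitude = 0` gives a demixing index of ≈ 0.71
and a tail energy of ≈ −919 kJ/mol-labelled units: the silent droplet
stays condensed, the pulsed field melts it.

A command-line wrapper exposes every stage
(`inst/cli/sonocryst fit-cnt --condition ultrasound --mw 340.12
--density 1.6 --split 2.05 --out-csv fit.csv --out-json fit.json`).

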