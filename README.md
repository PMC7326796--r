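# fibrilsans

Small-angle neutron scattering (SANS) analysis of wood cell-wall
nanostructure: from 2D detector frames to cellulose elementary-fibril
(EF) spacing and mid-q structure metrics.

## Who this is for

Researchers studying the deconstruction of lignocellulose — brown-rot
fungal decay, chelator-mediated Fenton (CMF) oxidation, delignification,
enzymatic treatment — with SANS, and anyone who needs a tested, scripted
replacement for interactive beamline reduction/fit workflows. The package
covers:

* **Reduction** — per-pixel q = 4π sin(θ)/λ mapping, monitor/dark/
  sensitivity/background corrections, two-fold anisotropy detection,
  sector averaging into *aligned*, *amorphous* or *isotropic* 1D
  profiles, and merging of the two instrument configurations
  (1.7 m and 14.5 m sample-to-detector; q = 0.003–0.27 Å⁻¹, λ = 6 Å,
  Δλ/λ = 13%).
* **Modeling** — the composite empirical model
  I(q) = C₁q^(−P₁) + [G e^(−q²R_g²/3) + B(q*)^(−P₂)] +
  A e^(−(q−q₀)²/2w²) + bkg (low-q power law, mid-q unified/Beaucage
  level, Gaussian diffraction peak), with wavelength-spread smearing.
* **Staged fitting** — aligned-minus-amorphous subtraction, two-level
  fits for P₁ and q₀, three-level fits for R_g and P₂, fixed-parameter
  protocol for weak-featured samples, and χ² < 1.06 χ²_min profile
  uncertainty intervals.
* **Reporting** — EF spacing d = 2π/q₀ (nm), treatment-to-treatment
  percent changes, q-region classification, and study-level tables.
* **Synthetic data** — seeded, ground-truth-labelled detector frames and
  profiles (CMF pulse-series and fungal decay-series scenarios) so the
  whole chain is testable with no instrument data.

## Worked example

Simulate the CMF pulse-series study (four wood disks: untreated, then
1/2/4 Fenton pulses), reduce and fit every frame, and compile the report:

```r
library(fibrilsans)

scen <- pulse_series_scenario(seed = 1)
res  <- analyze_scenario(scen)
print(res$report)
```

```
Sample                 P1 (low-q)     Rg nm (mid)  P2 (mid)     EF spacing nm
UW                     3.95           34.41        3.67         4.66
UW-CMF-1               3.73           9.03         1.61         5.11
UW-CMF-2               3.59           7.91         2.11         6.41
UW-CMF-4               3.38           6.00         2.51         7.70
```

Reading the table: each Fenton pulse erodes the matrix around the
cellulose elementary fibrils, so their packing distance d grows
(4.66 → 7.70 nm, a ~51% increase from 1 to 4 pulses), the low-q exponent
P₁ falls (rougher large-scale interfaces), the mid-q aggregate size R_g
shrinks and its exponent P₂ rises toward mass-fractal values. The
untreated control has no real mid-q feature — its R_g/P₂ column is
meaningless by construction (see the methods vignette) — and the ground
truths here are recovered within ~1–2%:

```r
d <- res$report$d_nm
relative_change_pct(d[2], d[4])   # 50.9 (% spacing increase, 1 -> 4 pulses)

fit <- res$analyses[["UW-CMF-1"]]$two_level
ef_spacing_nm(fit$params$peak_center)  # 5.11 nm from q0 = 0.1231 1/A
```

Individual stages are exposed as plain functions operating on
`detector_frame` / `profile1d` objects: `correct_frame()`,
`detect_anisotropy()`, `sector_reduce()`, `merge_profiles()`,
`subtract_amorphous()`, `fit_two_level()`, `fit_three_level()`,
`profile_uncertainty()`, `compile_report()`. Frames and profiles
round-trip through plain-text formats (`write_frame()`,
`write_profile()`, `write_fit_result()`), and a small CLI wraps the
generator and reporter:

```sh
Rscript inst/cli/fibrilsans.R simulate --scenario pulse-series --seed 1 --out sim/
Rscript inst/cli/fibrilsans.R report --fits fits/ --metadata samples.csv --out report
```

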