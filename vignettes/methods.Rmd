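---
title: "Methods: SANS nanostructure analysis of wood cell walls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SANS nanostructure analysis of wood cell walls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilsans)
```

## Scientific setting

Small-angle neutron scattering (SANS) probes structure on the 1–200 nm
scale through the intensity I(q) as a function of the scattering vector
q = 4π sin(θ)/λ. In wood cell walls, the regular lateral packing of
cellulose elementary fibrils (EFs) in the S2 layer produces a diffraction
peak at q₀, so the center-to-center EF spacing follows directly as
d = 2π/q₀. Because the fibrils are preferentially oriented along the
grain, that peak appears only in an azimuthally localized ("aligned")
portion of the 2D detector pattern, while unoriented cell-wall polymers
(hemicellulose, lignin, disordered cellulose) scatter isotropically
("amorphous"). Deconstruction treatments — brown-rot fungal decay,
chelator-mediated Fenton (CMF) oxidation, delignification, enzyme
cocktails — loosen the EF packing (d grows), fragment the matrix
(mid-q features change), and roughen large-scale interfaces (low-q slope
changes). `fibrilsans` implements the full analysis chain that turns raw
detector frames into these nanostructure metrics, plus a synthetic-data
generator with known ground truth so the chain is testable end to end.

## The composite empirical model

Reduced 1D profiles are described by a sum of empirical terms:

* a **low-q power law** C₁ q^(−P₁), capturing surfaces and lamellar
  structure larger than ~200 nm. P₁ near 4 indicates smooth interfaces
  (Porod scattering), lower values rougher or mass-fractal structure;
* a **mid-q unified (Beaucage) level** joining a Guinier regime of size
  R_g to a power-law regime with exponent P₂:
  G exp(−q²R_g²/3) + B (q*)^(−P₂), with
  q* = q/[erf(q R_g /√6)]³. This describes nanoscale aggregates and
  fragments (e.g. repolymerized lignin nodules, EF fragments);
* a **Gaussian diffraction peak** A exp(−(q−q₀)²/2w²) from the EF
  packing; and
* a flat **background**.

The unified level is implemented in its canonical published form with no
empirical sharpening correction (the `k` argument of
`unified_level_term()` exists and defaults to 1); the mid-q literature
does not publish a specific variant for this instrument, and level
coupling/cut-off schemes used by some packages are deliberately omitted —
the terms are independent and additive. The peak is Gaussian in q rather
than in d-spacing; for the narrow peaks involved (w/q₀ ≈ 0.1) the
d-space asymmetry is negligible. All intensities share one arbitrary
unit: no absolute calibration is attempted.

Parameter ranges are enforced as invariants: prefactors and amplitudes
non-negative, 1 < P₁ ≤ 4.5, 0 < P₂ ≤ 4, R_g, q₀, w > 0, motivated by
the span of values such treatments produce (P₁ up to 4.59, P₂ down to
1.2).

## Reduction conventions

* **Pixel geometry.** Pixel centers sit at 0-based integer coordinates;
  azimuth is measured counterclockwise from the detector +x axis; the
  scattering vector of a pixel at radial distance r is computed exactly,
  q = 4π sin(arctan(r/L)/2)/λ.
* **Corrections.** I = ((counts − dark)/sensitivity)/monitor −
  background, with Poisson uncertainties from the raw counts only.
  Dark, sensitivity and background maps are treated as exact: counting
  statistics dominate for these instruments and no error model for the
  calibration inputs is available.
* **Anisotropy detection.** The amplitude of the second circular harmonic
  of the azimuthal intensity in an annulus, divided by the azimuthal
  mean. Fibre scattering is two-fold symmetric, so the second harmonic is
  the right statistic; its phase gives the lobe azimuth. The default
  threshold (0.1) cleanly separates the generator's isotropic
  (score ≈ 0.001 at realistic counting statistics) and anisotropic
  (score ≳ 0.15) worlds. The annulus should stay inside the detector's
  inscribed circle: partial azimuthal coverage at the corners biases the
  harmonic.
* **Sector reduction.** Nearest-bin assignment of pixels to linear q bins
  (100 per configuration by default), no sub-pixel splitting, so that an
  independent per-pixel loop reproduces the reduction exactly. Bin
  intensity is the mean of contributing pixels; the reported q is the
  mean pixel q of the bin, which removes the first-order binning bias on
  steep curves. Sector wedges default to half-width 25° about the
  detected lobe azimuth (aligned) and 90° away (amorphous), both pooled
  with their 180° mirrors; the beamline's own sector angles are
  unpublished, so these are configurable defaults consistent with
  published reduction figures.
* **Configuration merging.** The short-distance (high-q) curve is scaled
  by the median intensity ratio over the q overlap onto the
  long-distance curve; the median is robust to noise and to the peak
  sitting inside the overlap.

## Staged fitting protocol

Anisotropic samples: the amorphous profile is interpolated onto the
aligned grid and subtracted, removing the mid-q contribution common to
both sectors and enhancing the peak. The subtracted curve is fitted with
**two levels** (power law + peak + background) for P₁ and q₀; the
amorphous curve is fitted with **three levels** (power law + unified +
background) for R_g and P₂. Isotropic samples get the three-level fit
only; weak-featured samples can have parameters held fixed
(`fit_config(fixed = list(pl_exponent = 3.6))`), and fixed values are
flagged in reports with the conventional `**` marker.

Numerical choices:

* **Weighting.** 1/σ² in linear intensity space. Linear (not log) space
  preserves the Poisson meaning of σ and accommodates the negative
  intensities that subtraction legitimately produces. All-zero σ columns
  fall back to unit weights with a warning.
* **Optimizer.** Bounded L-BFGS-B with intensity-scale parameters
  (prefactors, R_g, w, background) optimized in log₁₀ space. The start
  is deterministic: q₀ from the subtracted-intensity argmax over
  0.05–0.3 Å⁻¹, w = 0.2 q₀, P₁ from the log–log slope over q ≤ 0.01,
  R_g from a mid-q Guinier line on the power-law-subtracted residual,
  prefactors from window-edge evaluations. The q₀ window extends below
  the conventional 0.1 Å⁻¹ high-q boundary because spacings near 8 nm
  put the peak at q₀ ≈ 0.08 Å⁻¹. Because a strong Guinier plateau can
  contaminate the low-q slope estimate, a *fixed* list of alternative
  starts (P₁ ∈ {3.0, 3.9}, prefactor anchored to the lowest-q point) is
  also tried and the best final χ² wins — deterministic multi-start, no
  random restarts, so results are reproducible without seeds.
* **Resolution.** The generator smears curves with the instrument's
  wavelength spread (σ_q/q = (Δλ/λ)/(2√(2 ln 2)) ≈ 0.055 for
  Δλ/λ = 13%). Plain `fit_two_level()`/`fit_three_level()` ignore
  smearing by default, matching common beamline practice, with an opt-in
  `smear_frac`; the `analyze_sample()` pipeline *opts in* using the
  wavelength spread recorded in the frame metadata, since there the
  resolution is known exactly. Smearing with a q-proportional kernel
  preserves power-law slopes and peak centers to first order, so the
  default-off choice biases mainly the fitted peak width.
* **Uncertainties.** The fractional χ²-band rule: the interval on a
  parameter is the range over which the profiled χ² (all other free
  parameters re-optimized) stays below 1.06 χ²_min, endpoints bracketed
  by bisection to 1% of the parameter value. The reference value in the
  published rule ("χ²_critical") is ambiguous; it is interpreted here as
  the best-fit minimum, which matches the fractional-band behaviour of
  the IGOR/IRENA-style tooling this protocol descends from and makes the
  band collapse to the best fit as the ratio → 1. On a quadratic χ²
  surface the half-width then has the closed form √(0.06 χ²_min/c) with
  c the profiled curvature, which the acceptance suite verifies.

## The synthetic world

`pulse_series_scenario()` encodes four anisotropic disk samples whose
recoverable truths are published untreated / 1 / 2 / 4-pulse CMF values
for pine sapwood: EF spacings {4.66, 5.11, 6.40, 7.70}
nm, P₁ {3.91, 3.72, 3.57, 3.40}, R_g {—, 9, 7.9, 6} nm, P₂
{—, 1.6, 2.1, 2.5}. `decay_series_scenario()` encodes three isotropic
shaving samples (0/18/42 days of *G. trabeum* decay) with P₂
{1.2, 1.8, 2.4}, R_g 8 nm where reported, fixed-P₁ (3.6) metadata for
the decayed rows, and a diffraction peak capped at 5% of the local
amorphous intensity — below detectability, as observed for decayed
material.

Every quantity those measurements do not pin down is a fixed scenario
default, chosen once for realism and documented here:

| quantity | default | rationale |
|---|---|---|
| amorphous power-law prefactor C₁ | 5×10⁻⁷ (a.u.) | puts low-q intensity ~10³–10⁴ × background, typical of wood SANS |
| aligned/amorphous C₁ ratio | 2 | oriented material roughly doubles the low-q excess in the aligned sector |
| peak amplitude A | 0.5 (a.u.) | peak ≈ 2–3 × local continuum in the subtracted curve, echoing published profiles |
| peak width w | 0.12 q₀ | narrow but resolvable against the 5.5% instrumental σ_q/q |
| unified G | 30 (a.u.) | Guinier term dominates the mid-q decade |
| unified B | anchored so the tail is 0.1 a.u. at q = 0.1 Å⁻¹ | keeps P₂ identifiable against the background |
| background | 0.05 (a.u.) | high-q plateau visible in both configurations |
| azimuthal lobe width σ_φ | 20° | visibly localized arcs; keeps aligned-lobe leakage into the 90°-away amorphous sector below ~0.5% |
| expected counts per frame | 2×10⁷ | a generous high-flux acquisition; bin-level relative errors ≲ 1% |
| detector | 128×128 px, 8 mm pitch, beam center (63.5, 63.5) | 1 m-class detector covering 0.003–0.036 Å⁻¹ at 14.5 m and 0.012–0.27 Å⁻¹ at 1.7 m with λ = 6 Å |

Frames are generated by evaluating the smeared amorphous model at each
pixel's q, adding the aligned-model excess inside two-fold Gaussian
azimuthal lobes, masking pixels below the configuration q_min
(beamstop), scaling the grid to the expected total counts, and drawing
Poisson counts from a seed derived deterministically from the scenario
seed (sample × configuration streams). The monitor value is set so the
corrected frame returns to model intensity units.

### What the generator does *not* emulate

Real frames include detector non-uniformity beyond a smooth sensitivity
map, transmission and solid-angle corrections, multiple scattering,
incoherent hydrogen background structure, sample misalignment inside the
cell, and polydispersity of the EF lattice (the real peak is not exactly
Gaussian). A green round-trip test therefore establishes that the
reduction and fitting chain is *self-consistent and unbiased for data of
the stated form at realistic counting statistics* — not that the
pipeline reproduces the published table values, which derive from
externally deposited beamline data whose exact fit windows are
unreported.

## Known limitations

* The three-level fit on a sample with no real mid-q feature (the
  untreated control) is intentionally degenerate; its R_g/P₂ output is
  meaningless and such rows are reported without mid-q values.
* B and the flat background are nearly collinear over the single high-q
  decade available; at poor counting statistics P₂ inherits that
  degeneracy. The tail-anchoring default above keeps the synthetic world
  identifiable.
* Residual systematics of order a few tenths of a percent remain in
  reduced profiles (within-bin convexity at the steepest low-q bins,
  merge-scale interpolation), so reduced χ² on frame-derived profiles at
  2×10⁷ counts can exceed 1 even for a correctly specified model;
  parameter recovery is unaffected at the tested tolerances.
* `profile_uncertainty()` re-optimizes per scan point and costs many
  fits per parameter; the pipeline computes intervals only on request.
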