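---
title: "Methods: empirical prompt-gamma emission and PGS spectral analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical prompt-gamma emission and PGS spectral analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptgamma)
```

## The problem

Prompt gamma-ray spectroscopy (PGS) verifies proton range in vivo by
counting the discrete de-excitation photons produced when beam protons
excite tissue nuclei. The information carriers are a handful of lines — the
carbon 4.44 MeV (2⁺→0⁺) and oxygen 6.13 MeV (3⁻→0⁺) de-excitations above
all — whose intensities scale with how much path the proton spends at
energies where the corresponding production cross section is large. General
transport codes disagree on these lines, so this package implements a
deliberately transparent alternative: an empirical emission model driven by
parameterised excitation functions, wrapped in exactly the analysis chain a
PGS experiment uses.

## Proton transport

Transport is one-dimensional continuous slowing down along the beam axis.
The stopping power is the relativistic Bethe formula without shell or
density corrections, with Bragg additivity over the elemental composition
and a single material mean excitation energy (74 eV for the default PMMA,
C₅O₂H₈, ρ = 1.19 g/cm³, mass fractions H 0.080538 / C 0.599848 / O
0.319614). This is accurate at the percent level over the 2–250 MeV window
the package targets, which is sufficient: the emission model consumes only
the per-step pairs (Δx, E_kin), and millimetre-scale range accuracy is far
below the line-yield uncertainties of interest.

```{r}
csda_range(c(89.91, 129.52), pg_pmma())
```

Key choices:

* **Low-energy cutoff** `e_cut = 2` MeV, where the uncorrected Bethe
  formula loses validity; the remaining path is represented by a constant
  residual range `r_residual = 0.007` cm (negligible against the
  centimetre-scale ranges, configurable).
* **Step control**: at most 1% fractional energy loss per step, so
  σ_PG(E) is effectively constant within a step. Each step's length is the
  Simpson-rule evaluation of ∫dE′/S(E′) across the step's energy loss,
  which makes the summed path converge to the quadrature CSDA range well
  below the per-step truncation (halving the step moves the total by
  < 0.1%).
* **No lateral physics**: multiple Coulomb scattering and nuclear
  attenuation of the primary fluence are omitted. In a laterally infinite
  slab the line yield depends only on (Δx, E_kin), so the transverse beam
  FWHM is carried as metadata only.
* **Straggling** (Gaussian per-step energy-loss smearing) exists behind a
  flag but is off by default: deterministic transport makes every
  trajectory identical, which both simplifies testing and enables the
  binomial sampling shortcut below.

## The emission model

For every transport step and every catalogue line the mean free path is
λ = 1/(n σ_PG(E_kin)), with n the number density of the line's target
element (ρ w N_A / A) and σ in cm² (1 mb = 10⁻²⁷ cm²). The step emits with
cumulative probability p = 1 − exp(−Δx/λ); a uniform random number decides
acceptance; accepted steps add a photon with exactly the line energy and an
isotropic direction. Design decisions taken where the model description is
open:

* **One Bernoulli trial per (step, line)**, independent across lines;
  several lines may fire in the same step. Emissions are rare (p ≲ 10⁻⁴
  per step), so correlations are negligible.
* **Emission does not perturb the primary** — no energy is subtracted, no
  cascades are generated. The model adds photons for downstream processing
  only.
* **E_kin at step start** (not midpoint) evaluates the cross section; with
  1% energy-loss steps the difference is far below the excitation-function
  uncertainty.
* **Isotropic angular emission** by default, matching the observation that
  measured PG emission is close to isotropic; the direction sampler is a
  single replaceable function.

Excitation functions are exponentially modified Gaussians in proton energy:
a unit-area Gaussian N(μ, σ) convolved with a one-sided exponential (mean
τ) decaying toward *higher* energy, scaled by an area A (mb·MeV) and
clipped below a reaction threshold. This shape rises steeply above
threshold, peaks, and decays slowly — the generic morphology of
line-production excitation functions — and it is evaluated in the log
domain through the erfc closed form, so the far tail is numerically stable
(verified against direct quadrature of the defining convolution to 10⁻⁶
relative). `fit_xsec()` fits (A, μ, σ, τ) to tabulated cross sections by
Levenberg–Marquardt least squares with a small multi-start, because the
(μ, σ) ↔ τ trade-off makes the least-squares surface multimodal when the
rise is sparsely sampled.

The packaged catalogue values are *configuration, not ground truth*: they
were chosen by the package authors to resemble published excitation
functions in peak position, magnitude and high-energy tail, and every
number is editable YAML. Two lines are handled specially:

* the **2.22 MeV hydrogen neutron-capture** line arises from secondary
  neutrons, which this package does not transport; it is injected as a
  configurable constant yield per primary (default 2×10⁻³, with uniform
  depth along the track), as is the 0.511 MeV annihilation line
  (default 4×10⁻³);
* the **6.05 MeV oxygen E0 transition** is present in the catalogue but
  flagged `single_photon_allowed = FALSE`: a 0⁺→0⁺ transition cannot emit
  a single photon (it proceeds by internal conversion), and the sampler
  enforces this unconditionally.

With straggling off, all primaries share one trajectory, so the number of
emissions per (step, line) across N primaries is Binomial(N, p).
`sample_emission_counts()` samples those binomials directly instead of
looping over primaries — distribution-identical for line counts and origin
depths, and what makes 10⁷–10⁸-primary spectra take seconds. The
per-primary Bernoulli path (`sample_emissions()`) remains the reference
implementation and the two are cross-checked statistically in the tests.

## Detector response

The detector is parametric, not a photon-transport model: absolute
magnitudes of measured spectra depend on the full detector geometry and
efficiency and are explicitly out of scope. An emitted photon is tested
against the solid angle of the crystal front face (a 3.8 cm diameter disk
25 cm from the axis, side-on, deterministic ray–disk intersection); an
accepted photon then deposits its full energy, E − 0.511, E − 1.022, a
uniform draw from (0, Compton edge], or nothing, with configurable branch
fractions (defaults 0.35 / 0.12 / 0.08 / 0.30; escape branches only open
above the 1.022 MeV pair threshold, their mass folding into the full-energy
branch below it). Deposits are smeared with a Gaussian of
FWHM(E) = a√E + b·E (defaults a = 0.028 MeV^½, b = 0.005, giving ≈ 4%
relative FWHM at 0.662 MeV, typical of CeBr₃) and histogrammed on
left-closed 1024-bin edges over 0–10 MeV. Normalization divides by the
number of primaries and the bin width, yielding counts · primary⁻¹ · MeV⁻¹.

## The synthetic acquisition chain

`generate_traces()` emulates event-by-event waveform acquisition: 200 ns
windows sampled every 4 ns (50 samples), each containing 0–3 EMG-shaped
pulses on a constant baseline with additive white Gaussian noise, returned
together with the ground-truth ledger. What it deliberately does **not**
emulate: ADC quantisation and saturation, trigger logic, gain drift,
correlated (non-white) noise, and pile-up closer than the fitter can
resolve — in the default emulation pulses in one window are spaced by
≥ 30 ns. Passing tests therefore demonstrate that the analysis chain
recovers what this generator produces, not that it would survive every
pathology of real electronics.

The analysis follows the experimental recipe:

1. **Baseline restoration** subtracts the median of the first 5 samples.
2. **Pulse fitting** runs model selection over 0–3 EMG components:
   candidate locations are local maxima above 5× the noise σ, each count is
   fitted by Levenberg–Marquardt, and the small-sample information
   criterion (AICc, 4 parameters per pulse) picks the winner. Areas,
   apexes, widths and relaxation times are reported per pulse with a
   per-trace adjusted R².
3. **Quality filtering** keeps pulses with adjusted R² above a threshold
   and relaxation time inside a window — scintillator pulses have a
   characteristic decay constant, so off-window τ flags glitches — plus an
   optional time gate on the acquisition timestamp standing in for in-spill
   selection (spill structure is facility-specific).
4. **Spectrum building** histograms pulse areas or apexes (both modes
   implemented; the choice is a flag, since either statistic is
   proportional to deposited energy for a fixed pulse shape).
5. **Dead time** is corrected with the non-paralyzable model
   n = m/(1 − mτ_dead); τ_dead is configuration.
6. **Calibration** is a least-squares linear channel→energy map (degree 2
   available) anchored on known lines: the annihilation peak, the hydrogen
   capture line, the carbon 4.44 MeV line and its escape peaks. In the
   end-to-end emulation the anchor channels are found by SNIP-subtracting
   the channel spectrum and rank-matching the strongest peaks to the sorted
   anchor energies.

## Line quantification

`snip_baseline()` implements ascending-window SNIP: for p = 1…p_max each
bin is clipped to min(vᵢ, (vᵢ₋ₚ + vᵢ₊ₚ)/2), optionally in the
log-log-sqrt-compressed (LLS) domain v → log(log(√(v+1)+1)+1), which
protects small peaks on a large dynamic range. Defaults: LLS on, p_max of
roughly twice the broadest peak FWHM in bins. The ascending variant and the
LLS operator are the common spectroscopy defaults; both are exposed.
A final guard clips the baseline to never exceed the spectrum.

`fit_lines()` fits a sum of area-parameterised Gaussians (optional linear
residual term, optional shared width — off by default, since per-component
widths are the safer general choice) to the baseline-subtracted spectrum in
each region of interest; net areas integrate the fitted components and
uncertainties come from the fit covariance. Default regions span ±3
expected detector sigmas around each catalogue energy. `yield_curve()`
applies this per beam energy and returns a tidy table.

## Numerical choices and degenerate inputs

* Range quadrature: `stats::integrate` at 10⁻⁹ relative tolerance; failure
  raises an error carrying the quadrature diagnostics.
* EMG evaluation: log-domain erfc form everywhere; zero amplitude
  short-circuits; non-finite parameters are rejected.
* All-zero cross-section tables fit to A = 0 without invoking the
  optimiser; optimiser failures return a flagged, non-converged result
  carrying the starting values rather than throwing.
* Pure-noise traces select zero pulses via the AICc floor; degenerate
  optimiser failures yield a flagged zero-pulse row.
* Saturated dead-time input (mτ ≥ 1) is a hard error, not a clamp.
* Seeds: one global seed is expanded into independent per-stage streams
  (`stage_seed`), all below 2³¹, so stages re-run in isolation reproduce
  their outputs; deterministic stages consume no randomness.

## Problem sizes in the shipped tests

The test suite validates the accept–reject sampler against closed forms at
10⁵ single-step primaries and 120 seeded full-trajectory repeats; the
end-to-end yield-trend check sweeps the five-energy grid at 3×10⁷ primaries
per energy through the binomial path; trace-level recovery studies use
100–500 synthetic traces; the doublet-resolution study uses 100 seeded
spectra. These sizes were chosen so the whole suite runs in well under a
minute per file on a laptop-class core while keeping Monte-Carlo
uncertainties a factor ≥ 3 below each tolerance being asserted.

The yield-trend check deserves a note: with the default (plateauing)
excitation functions the expected per-primary yields still increase with
beam energy — the deterministic sum of step probabilities confirms it — but
the increments between neighbouring grid energies are 1–6% for carbon and
below 1% for oxygen, far below what any desk-scale photon count can resolve
end to end. The end-to-end monotonicity test therefore runs under
excitation functions that are non-decreasing below the sweep energies (EMG
centroid above 130 MeV), the regime the trend statement is conditional on,
where the increments are order-unity.

## Known limitations

* No neutron or secondary-particle transport: secondary-process lines are
  constant-yield injections, so their depth profiles and energy dependence
  are not predictive.
* No angular-differential cross sections; no Doppler broadening of the
  4.44 MeV line.
* The parametric detector has no intrinsic-efficiency energy dependence by
  default and no pile-up at the histogram level; absolute line magnitudes
  are not comparable to measurements.
* Calibration anchor matching is rank-order based and assumes the anchor
  lines are the strongest peaks of the channel spectrum.
* The transport is a slab model: heterogeneous or voxelised targets are out
  of scope.
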