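---
title: "Transition dipole strength analysis of 2D IR and FTIR spectra"
author: "tdsir package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition dipole strength analysis of 2D IR and FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsir)
```

## The problem

The transition dipole strength (TDS) of a vibrational mode — the squared
magnitude of its transition dipole moment, in debye squared (D²) — reports on
vibrational coupling and delocalization. For protein amide I′ modes it
separates secondary structures that absorb at the same frequency: a localized
or disordered amide I′ mode sits near 0.12 D², α-helices reach 0.26–0.55 D²,
and β-sheets span roughly 0.25–1.25 D² depending on sheet size and
organization. FTIR is largely blind to coupling-induced TDS changes because
the integrated linear absorption is conserved, but 2D IR is not: diagonal 2D
IR intensity scales as μ⁴ while the linear optical density (OD) scales as μ²,
so the ratio of the two isolates μ².

Two practical obstacles limit routine TDS analysis. First, the linear OD of
dilute protein samples rides on a large, sloped solvent/cell background, and
dividing by a poorly corrected OD turns every baseline zero-crossing into a
huge artifact in the TDS spectrum. Second, the pump pulses of a 2D IR
spectrometer do not have a flat intensity profile, which biases TDS values for
modes far from the calibrant frequency. This package automates both
corrections and validates the whole chain end-to-end on synthetic data with
known ground truth.

## The TDS equation

For a sample diagonal slice ΔOD(ω, ω) and baseline-corrected linear OD(ω),
with a calibrant of known dipole strength |μ|²~cal~ and band maximum ω~max~,

d(ω) = [ ΔOD~s~(ω, ω) / OD~s~(ω) ] /
       [ ΔOD~cal~(ω~max~) / OD~cal~(ω~max~) ] · |μ|²~cal~ ·
       I~pump~(ω~max~) / I~pump~(ω).

`computeTDS()` assembles this from `ratioSpectrum()` (with a near-zero-OD
guard), a `CalibrantReference` and `pumpNormFactor()`. Three structural
properties follow directly from the equation and are enforced by tests:

* **Calibrant self-consistency** — measuring the calibrant as its own sample
  returns |μ|²~cal~ at ω~max~ exactly, for any pump, because the pump factor
  is 1 at ω~max~.
* **Concentration invariance** — OD scales as c·μ² and the 2D diagonal as
  c·μ⁴, so the concentration factor c cancels point by point.
* **Pump exactness** — the final factor exactly undoes a non-flat pump
  envelope; it is the identity for a flat pump. Note that ω~max~ in the pump
  factor is the *calibrant's* band maximum (where the calibration was
  evaluated), not the maximum of the pump envelope; the two coincide only by
  accident.

The FTIR route for uncoupled calibrant modes is
D = 9.184×10⁻³ ∫ ε(ν)/ν dν (ε in M⁻¹cm⁻¹, ν in cm⁻¹, D in D²), implemented as
trapezoidal quadrature in `dipoleStrengthFTIR()` with integration limits from
`findPeakBounds()`.

## Baseline correction

`airPLS()` implements adaptive iteratively reweighted penalized least
squares. Each iteration solves the weighted Whittaker problem
(W + λD′D) z = W s exactly (sparse Cholesky, second-difference penalty), then
reweights: points at or above the baseline — candidate peaks — get weight 0,
points below get weight exp(t·|sᵢ−zᵢ|/|d|) where |d| is the L1 norm of the
negative residuals. Iteration stops when |d| < 0.1% of |s| (both L1 norms) or
after `maxIter` (default 15) iterations.

Numerical behavior worth knowing, all verified by the test suite:

* The converged baseline rides the *lower envelope* of the noise, sitting a
  couple of noise standard deviations below the mean background. The
  resulting small positive offset in the corrected OD is harmless for TDS
  work — it is the same offset the calibrant normalization tolerates — and is
  far preferable to the zero-crossings of least-squares polynomial fits,
  which explode the ΔOD/OD ratio.
* The smoothness penalty imposes natural boundary conditions: over a boundary
  layer of roughly λ^(1/4) points the baseline's curvature is flattened. For
  curved backgrounds the fit is excellent in the interior and deviates mildly
  at the spectrum edges; keep the analysis bands away from the edges.
* λ (default 1e5) is the one knob that matters. It is dimensionless in index
  space, so denser grids need larger λ for the same stiffness. For weak
  signals raise λ; the validation studies in this package use λ = 1e6 for
  501-point spectra spanning 250 cm⁻¹.
* Lineshapes with slowly decaying Lorentzian wings (pseudo-Voigt η ≳ 0.5) are
  a known limitation: the reweighting treats the wings as background, pulling
  the baseline up near the band and biasing the recovered apex by 3–7%
  regardless of λ. Gaussian-like (inhomogeneously broadened) bands do not
  show this bias.

`savgolSmooth()` (Savitzky–Golay, default 15-point window, 3rd-order
polynomial) is available for noisy OD data and is applied *before* airPLS
when `correctBaseline(..., presmooth = TRUE)`. Edges are handled by fitting
the same-order polynomial over the truncated available window — no data is
fabricated beyond the spectrum ends, at the cost of less smoothing there.
Smoothing is applied to the linear OD only, never to ΔOD or to the TDS
spectrum itself, where oversmoothing can erase fine structure. The
range-restricted `polynomialBaseline()` reproduces the manual-correction
pathway the automated method is benchmarked against.

## The synthetic-data generator

No instrument data ships with the package, so `synthDataset()` generates
mutually consistent spectra in which the ground truth is embedded by
construction: band k contributes A_k(ω) = c_k·μ²_k·g_k(ω) to the OD (unit-peak
lineshape g, concentration-like amplitude c), the 2D diagonal is
κ·I~pump~(ω)·Σ μ²_k·A_k(ω), and the calibrant is a noiseless, baseline-free
single band from the same model. Running the full pipeline on such a dataset
must return μ²_k at each isolated band maximum — exactly in the zero-noise
zero-background limit, and to within the stated tolerances otherwise.

Default study conditions (chosen once, from physical reasoning, and then held
fixed):

* axis 1500–1750 cm⁻¹ at 0.5 cm⁻¹ (501 points) — the amide I′ window;
* a quadratic background of ~0.2 OD with gentle slope and curvature — the
  dominant "background" a real linear OD carries;
* additive white Gaussian OD noise of sd 1.5×10⁻³ — instrument-limited
  absorbance noise after ~20 min of signal averaging; the paired 2D diagonal
  noise is 10⁻⁵ ΔOD;
* a Gaussian pump envelope centered at 1620 cm⁻¹ with 120 cm⁻¹ FWHM —
  a realistic broadband pulse profile;
* the validation band: a Gaussian carboxyl-stretch-like mode at 1623 cm⁻¹
  with μ² = 0.200 D² and 16 cm⁻¹ FWHM. The concentration ladder scales its
  amplitude 0.25 / 0.5 / 1 (apex OD 0.05 / 0.10 / 0.20), emulating the
  10 / 20 / 40 mM series of the small-molecule validation. The Gaussian
  shape reflects the inhomogeneous broadening of solution-phase small
  molecules; the generator's general default is pseudo-Voigt η = 0.5, whose
  Lorentzian wings exercise the documented airPLS limitation instead.

What the generator deliberately does **not** emulate: correlated or 1/f
noise, water-vapor lines, solvent absorption under the pump, scattering
backgrounds, cross-peaks and excited-state (overtone) lobes of the 2D
surface, and band-shape changes during aggregation. Passing the synthetic
suite therefore demonstrates the correctness of the *computation*, not
robustness against every artifact of real spectrometers.

Kinetics: `synthKinetics()` applies the same model frame by frame (66 s
cadence by default, timestamps at frame centers) with time-varying μ²(t)
and/or amplitude trajectories and independent per-frame noise. The
aggregation scenario ramps a single labeled-residue band sigmoidally from
0.13 D² (disordered, lag phase) to 0.26 D² (β-sheet, plateau) over ~2.5 h of
frames, with higher per-frame noise (6×10⁻³ OD) that the 15-frame window
averaging reduces by √15.

## Kinetics analysis

`windowAverage()` block-averages a series (default 15 frames, non-overlapping,
matching the ~16.5 min windows used for aggregation data; a smaller `stride`
gives overlapping windows). Output times are window midpoints; a trailing
partial window is dropped. `intensityTrace()` reads the per-frame diagonal
|ΔOD| at one frequency (the conventional fibril-growth readout at
1623 cm⁻¹); `tdsTrace()` runs smoothing + airPLS + the TDS equation per
window and reads d at the requested frequency (nearest axis point by
default), emitting `NA` — never silently dropping — for windows masked by the
OD floor guard. The calibrant reference is evaluated once per experiment, not
per window.

## Numerical choices and degenerate inputs

* **Interpolation** is linear (1D) / bilinear (2D); extrapolation is always
  an error. All readers sort axes ascending; duplicate wavenumbers are
  rejected.
* **Masks** mark points where a computation was refused (e.g. corrected OD
  below 1% of its maximum — the floor that prevents ΔOD/0 artifacts). Masks
  propagate through arithmetic and resampling; reading a masked TDS point is
  an error, not an `NA` surprise.
* **Diagonal sign**: 2D IR diagonal fundamentals are bleaches; the extractor
  accepts either sign convention and returns magnitudes, erroring if a slice
  genuinely mixes signs beyond a 1% amplitude tolerance.
* **Peak bounds**: the zero-crossing rule is underdetermined for an isolated
  band on a flat baseline (the only derivative zero is at the maximum), so
  the bound search walks outward and stops at a derivative zero-crossing
  *or* at three consecutive points with |derivative| below 1% of its in-band
  maximum, whichever comes first; both thresholds are exposed as parameters.
  Ties between equally near local maxima resolve to the lower wavenumber.
* **Replicate spread**: `averageReplicates()` reports both the sample (n−1)
  and population (n) standard deviation, since published summary tables do
  not always state the convention.
* **Grubbs' test** is two-sided, single-outlier, α = 0.05 by default, with
  the critical value computed from the t distribution (agrees with published
  tables for n = 3–10 to 10⁻³).
* **SNR** uses the peak-height convention with a linearly detrended noise
  window, so residual baseline slope is not counted as noise. The window
  placement is user-specified; published SNR figures for comparable data are
  treated as descriptive, not as calibration targets.
* Degenerate inputs (all-zero weights, noiseless noise windows, constant
  Grubbs samples, empty fit ranges) raise classed errors
  (`tds_degeneracy_error` etc.) rather than producing NaN.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run entirely on generated data:
501-point spectra; 20 seeds per concentration-ladder level (3 levels); 10
seeds of 135-frame kinetics series (9 windows each); 50-seed sampling checks
for SNR calibration. These sizes give stable means for the stochastic checks
while keeping the full suite in the tens of seconds on a single CPU.

## Worked example

```{r example}
cfg <- synthConfig(
  bands = list(bandSpec(1623, 16, 0.200, shape = "gaussian")),
  calibrant = bandSpec(1623, 16, 0.200, shape = "gaussian"),
  seed = 7)
ds <- synthDataset(cfg)
cal <- calibrantFromSpectra(ds$calibrantDiag, ds$calibrantOD, mu2 = 0.200)
cb <- correctBaseline(ds$od, method = "airpls", lambda = 1e6,
                      presmooth = TRUE)
tds <- computeTDS(ds$diag, cb$corrected, cal, pump = ds$pump,
                  normalizePump = TRUE)
tdsAt(tds, 1623, mode = "local_max")
snrReport(cb$corrected, c(1610, 1636), c(1500, 1560))
```

## Known limitations

* Pseudo-Voigt wings bias airPLS baselines near the band (see above); for
  quantitative work on Lorentzian-like bands, restrict the window or fit the
  wings explicitly.
* No automatic λ selection is attempted; λ is a documented, exposed knob.
* The 2D container carries a single (diagonal-relevant) signal surface; no
  cross-peak, lifetime, or polarization analysis.
* The ΔOD diagonal is assumed to be the fundamental (bleach) lobe magnitude;
  overtone lobes are not modeled.
* Calibrant dipole strengths are user-supplied configuration (e.g. NMA near
  1623 cm⁻¹, 2H5NBA at 1585 cm⁻¹); the package hardcodes no calibrant table.
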