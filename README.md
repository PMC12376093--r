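# tdsir — transition dipole strength analysis for 2D IR / FTIR spectroscopy

`tdsir` computes absolute transition dipole strengths (TDS, in debye², D²) of
vibrational modes from two-dimensional infrared (2D IR) and FTIR spectra. TDS
probes vibrational coupling and delocalization, and for protein amide I′
modes it distinguishes secondary structures that plain frequency analysis
cannot: a disordered amide I′ mode sits near 0.12 D² while β-sheet modes
reach 0.25–1.25 D². The package is aimed at 2D IR practitioners who want the
whole chain — baseline correction, calibrant scaling, pump normalization,
kinetics — automated, reproducible, and testable without instrument data.

The core quantity is the calibrant-scaled ratio of nonlinear to linear
signal. With a sample diagonal slice ΔOD(ω, ω), baseline-corrected linear
OD(ω), a calibrant of known |μ|²₍cal₎ with band maximum ω₍max₎, and pump
envelope I₍pump₎:

    d(ω) = [ΔOD_s(ω,ω)/OD_s(ω)] / [ΔOD_cal(ω_max)/OD_cal(ω_max)]
           · |μ|²_cal · I_pump(ω_max)/I_pump(ω)

Because the 2D diagonal scales as μ⁴ and the linear OD as μ², d(ω) at a band
maximum is that mode's dipole strength, independent of concentration. For
calibrants measured by FTIR, D = 9.184×10⁻³ ∫ ε(ν)/ν dν (trapezoidal
integration between first-derivative-determined band limits).

The fragile step is the linear OD baseline: dividing by a corrected OD that
crosses zero sprays artifacts across the TDS spectrum. `tdsir` implements
airPLS (adaptive iteratively reweighted penalized least squares — a weighted
Whittaker smoother whose weights are iteratively driven to zero in peak
regions) for automated full-window background correction, optional
Savitzky–Golay noise filtering (15-point, 3rd order), and the manual
polynomial pathway for benchmarking. A synthetic-data generator emulates the
forward model (OD ∝ c·μ², diagonal ∝ c·μ⁴, polynomial backgrounds, white
noise, non-flat pump) so every stage is validated against embedded ground
truth. Quality-control helpers cover SNR, percent error, replicate summaries
and Grubbs' single-outlier test.

## Worked example

Generate a synthetic validation dataset (a Gaussian carboxyl-stretch-like
band with known μ² = 0.200 D² on a curved background), correct the baseline,
and compute the TDS spectrum:

```r
library(tdsir)
cfg <- synthConfig(
  bands = list(bandSpec(1623, 16, 0.200, shape = "gaussian")),
  calibrant = bandSpec(1623, 16, 0.200, shape = "gaussian"),
  seed = 7)
ds  <- synthDataset(cfg)
cal <- calibrantFromSpectra(ds$calibrantDiag, ds$calibrantOD, mu2 = 0.200)
cb  <- correctBaseline(ds$od, method = "airpls", lambda = 1e6,
                       presmooth = TRUE)
tds <- computeTDS(ds$diag, cb$corrected, cal, pump = ds$pump,
                  normalizePump = TRUE)
tdsAt(tds, 1623, mode = "local_max")
#> DipoleStrength: 0.2031 D^2 at 1623 cm-1 [tds_eq2]
snrReport(cb$corrected, c(1610, 1636), c(1500, 1560))
#> SNR = 214.9 (signal height 0.1969 / noise sd 0.0009166)
```

The recovered 0.2031 D² is within 1.6% of the embedded truth — the accuracy
regime the automated baseline correction is designed to deliver. Replicate
outliers are screened with Grubbs' test:

```r
grubbsTest(c(0.202, 0.195, 0.196, 0.241))
#> Grubbs' test (two-sided, n = 4, alpha = 0.05): G = 1.4850, critical = 1.4813
#>   value 4 is an outlier
```

The methods vignette (`vignettes/tds-analysis.Rmd`) documents the model, the
airPLS numerics (lower-envelope offset, boundary layers, the pseudo-Voigt
wing limitation), the generator's study conditions, and what the synthetic
validation does and does not demonstrate about real instrument data.

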