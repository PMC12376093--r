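Package: tdsir
Title: Transition Dipole Strength Analysis for 2D IR and FTIR Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated transition dipole strength (TDS) analysis for
    infrared spectroscopy of proteins. Implements adaptive iteratively
    reweighted penalized least squares (airPLS) baseline correction of the
    linear optical density, Savitzky-Golay noise filtering, dipole strength
    determination from FTIR extinction spectra by trapezoidal band
    integration, calibrant- and pump-normalized TDS spectra from the
    diagonal of 2D IR spectra, kinetics analysis of aggregation time series,
    quality-control statistics (signal-to-noise, percent error, Grubbs'
    outlier test), and a synthetic-spectrum generator with embedded
    ground-truth dipole strengths for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spectrum1d-methods.R'
    'spectrum2d-methods.R'
    'io.R'
    'baseline.R'
    'ftir.R'
    'twodir.R'
    'kinetics.R'
    'stats-qc.R'
    'synth.R'
    'cli.R'
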