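Package: lvpwave
Title: Left Ventricular Pressure Waveform Analysis for Implantable Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for continuously recorded left ventricular
    pressure (LVP) from implantable telemetry, from raw transmitter output to
    per-beat contractility and relaxation indices and multi-day trend
    summaries. Includes transmitter calibration (affine fit to pressure-chamber
    points with ambient-pressure subtraction), beat detection with fiducial
    annotation driven by the pressure derivative, the eight classical
    monitored parameters per beat (heart rate, mean LVP, LVSP, LVEDP,
    dP/dt max, Vmax, -dP/dt max, and the 66%-decay relaxation time constant
    Tau), quality control with arrhythmia/artifact exclusion rules, 20-s epoch
    and 1-h moving-average aggregation with standard errors, and a synthetic
    hemodynamic waveform generator with analytically known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ggplot2,
    jsonlite,
    optparse,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
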