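Package: ccfs
Title: Cell-Cell Force Spectroscopy Curve Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for cell-cell force spectroscopy (CCFS)
    retract curves acquired by atomic force microscopy: baseline and
    contact-origin estimation, Savitzky-Golay derivative based rupture-event
    detection, detachment work and adhesion metrics, aggregation of
    per-curve work by acquisition condition, and least-squares fitting of
    parametric models of detachment work versus delay time, setpoint force,
    approach speed and retract speed. Includes a stochastic simulator of
    CCFS retract curves (Hertzian contact trajectory, Poisson bond
    formation proportional to the time-integrated contact area, truncated
    normal rupture forces, viscous drag) so the full pipeline can be
    exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
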