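Package: presynq
Title: Presynaptic Calcium-Current and Quantal Release Analysis for Paired
    Calyx-of-Held Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired pre/postsynaptic voltage-clamp
    recordings at large glutamatergic terminals such as the calyx of Held.
    Fits presynaptic calcium-channel current-voltage relations with a
    Hodgkin-Huxley gating model on a Goldman-Hodgkin-Katz open-channel
    driving force, fits tail-current activation curves with a Boltzmann
    function, deconvolves EPSCs into quantal vesicle release rates with
    residual-current compensation, estimates readily-releasable and total
    releasable vesicle pools with a constant refilling correction, and
    quantifies docked-vesicle distributions at active zones from electron
    microscopy coordinate tables.  A synthetic-data generator with
    calibrated group presets provides ground truth for parameter-recovery
    testing of every stage, and standard group comparisons (Shapiro-Wilk,
    Bartlett, one-way ANOVA with Dunnett's post hoc test, unpaired t-test)
    are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    minpack.lm,
    multcomp,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
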