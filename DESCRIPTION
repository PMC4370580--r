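Package: ictalwave
Title: Wavefront Kinematics and Classification of Interictal Events in
    Voltage-Sensitive Dye Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for voltage-sensitive dye (VSD) imaged
    interictal epileptiform events in hippocampal-neocortical slices:
    per-pixel conditioning (background subtraction, detrending, 2x2 spatial
    binning, Savitzky-Golay differentiation), wavefront onset detection as
    +2SD threshold crossings with sub-frame interpolation, isochrone/onset
    maps projected onto anatomical axis paths, robust (Theil-Sen) propagation
    velocity estimation, saltatory-jump detection, conduction-time
    measurement, event-type classification (hippocampal non-propagating,
    neocortical non-propagating, propagating, and reverberating subtypes),
    and local field potential waveform morphology analysis (biphasic vs
    triphasic threshold-crossing counts, first-to-last crossing span,
    peak-to-peak amplitude, interlaminar delays).  A synthetic-data generator
    produces VSD movies, region atlases, and LFP traces with analytic
    ground-truth kinematics so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
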