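Package: silentsyn
Title: Quantitative Analysis of Silent Synapses, Cortical Maps, and Visual
    Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative procedures used to characterize
    AMPA-silent synapses and visual-cortex plasticity: the minimal-stimulation
    failure-rate estimator of the silent-synapse fraction, synaptic potency
    and success rate, AMPA/NMDA ratio and NMDA potency, mEPSC event detection
    with the 400-event/20-bin cumulative-distribution procedure, paired-pulse
    ratio, use-dependent NMDA-receptor block (MK-801) decay, strontium-evoked
    quantal analysis, pixelwise Fourier analysis of periodic-stimulus
    intrinsic-signal movies with ocular-dominance index computation and
    block-averaging rules, fluorescence puncta segmentation and
    colocalization-based synapse density, western-blot normalization, and
    visual-water-task threshold extraction.  Synthetic-data generators with
    known ground truth emulate every raw-data type so each analysis stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
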