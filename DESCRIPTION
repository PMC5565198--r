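Package: sceneprobe
Title: Probe-Insertion Psychophysics for Natural-Scene Segmentation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how local image reconstruction depends on
    object-segmentation structure versus raw edge energy in natural scenes.
    Builds paired bottom-up (edge-energy) and top-down (annotator-consensus)
    maps from grayscale scenes, selects categorized probe insertion points,
    synthesizes orientation-noise probe stimuli and global scene
    manipulations (filtering, warping, cut-out/lines, phase/power
    scrambling, gap stimuli), simulates model observers (quadrature-pair
    gain-control and linear-template signal-detection observers), and
    analyzes trial records via d-prime/criterion, rich/poor log-ratios,
    psychophysical reverse correlation, retuning indices, and double-pass
    internal-noise estimation. Includes a lateralized event-related
    potential analysis stage (contra-minus-ipsi differencing, rich-minus-
    poor modulation maps with across-subject Z-scores, window pooling) and
    synthetic-data generators for scenes, simulated cohorts, and EEG
    epochs, so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    signal,
    data.table,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
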