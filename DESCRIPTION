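Package: synpuncta
Title: Presynaptic Punctum Detection and Two-Channel Quantification in
    Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects presynaptic sites along traced neuronal processes in
    two-channel fluorescence images (a synaptophysin marker channel and a
    SNAP29 signal channel) by intensity normalization, global thresholding,
    8-connected component labeling, and area and process-distance filtering.
    Quantifies per-punctum SNAP29 intensity, marker-normalized intensity
    ratios, puncta density per micron of process, two-channel
    colocalization, and a bounded accumulation index along processes, and
    compares per-punctum intensity distributions across experimental
    conditions with the two-sample Kolmogorov-Smirnov test. Includes a
    ground-truthed synthetic image generator (Gaussian spots on smooth
    simulated processes, off-process distractors, sub-threshold speckle,
    additive background noise) so every stage of the pipeline is testable
    without raw micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
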