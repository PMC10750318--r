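Package: hjortheeg
Title: Hjorth Parameter Extraction and Clustering Analysis for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-domain feature extraction for segmented multichannel EEG
    recordings using the three Hjorth parameters (Activity, Mobility,
    Complexity), with a seeded band-limited synthetic EEG generator, CSV
    trial input/output in a motor-execution dataset layout (16 electrodes,
    125 Hz, 4-second trials), windowed per-electrode feature series, feature
    correlation analysis, k-means clustering with label-agreement scoring,
    and per-electrode task contrasts, tied together in a reproducible
    simulate/extract/analyze pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
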