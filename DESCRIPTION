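Package: screendetect
Title: Automatic Recognition of Screen-Plays from Player Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies screen-plays (the basic cooperative play
    in basketball) from multi-agent positional tracking data. Provides
    rule-based candidate segmentation around screener/user-defender contacts,
    a four-block 148-dimensional spatiotemporal feature scheme, soft-margin
    Gaussian-kernel support vector machine detection with one-against-all and
    one-against-one multi-class typing of off-ball screens, a repeated-split
    ROC/AUC and recall-precision evaluation protocol, and a synthetic
    five-on-five half-court trajectory simulator with planted screen motifs
    so the whole pipeline can be exercised without proprietary tracking
    feeds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
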