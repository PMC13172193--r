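Package: peroxdyn
Title: Peroxisomal Calcium Uptake and Motility Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis chain for live-cell studies of
    peroxisomal calcium uptake and peroxisome-ER tethering: bleed-through
    and background corrected ratiometric FRET calcium measurement under a
    two-step store-operated calcium entry (SOCE) stimulation protocol,
    single-particle linking of peroxisome detections with motility
    statistics, a random-intercept linear mixed-effects model with
    Satterthwaite degrees of freedom and stepwise backward model reduction,
    and IsoData-threshold/watershed peroxisome counting. A synthetic-data
    generator with known ground truth (calcium traces, rendered FRET
    channels, two-state Brownian trajectories, factorial mean-speed
    datasets, spot-field images) makes every stage verifiable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
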