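Package: mnvmorph
Title: Morphometry of Macular Neovascularization from OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the vascular architecture of macular neovascularization
    (MNV) in en-face OCT angiography images and relates it to long-term
    anti-VEGF treatment demand. Provides a synthetic-data module that grows
    branching vascular networks, rasterizes them into speckled angiograms, and
    simulates calibrated patient cohorts; a morphometry module extracting the
    four standard MNV parameters (area, total vascular length, box-counting
    fractal dimension, flow density) via ROI-restricted binarization,
    topology-preserving thinning, and centerline-graph measurement; a robust
    statistics module implementing percentile-fence outlier downweighting with
    geometric-mean weight combination feeding weighted linear and logistic
    regression; and a pipeline layer orchestrating simulate, quantify, and
    analyze stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
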