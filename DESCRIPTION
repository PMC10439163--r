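Package: microflowq
Title: Quantitative Image Analysis for Microfluidic Cellular Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Headless analysis toolkit for microscopy of cells and cell
    suspensions in microfluidic and static assays. Provides single-cell
    particle-tracking velocimetry (Crocker-Grier style centroid detection and
    trajectory linking), Shi-Tomasi/Kanade-Lucas-Tomasi optical-flow velocity
    time courses and spatial velocity profiles, brightfield and fluorescence
    cell-adhesion morphology and functionality scoring (including
    filopodia-like protrusion counting and nuclear lobe counting),
    multi-channel occlusion and accumulation quantification with automatic
    device-map inference, and k-means interpretation of pooled feature tables
    with scree and silhouette diagnostics. A synthetic-microscopy fixture
    generator renders ground-truthed imaging for every workflow so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    png,
    EBImage,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
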