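Package: fibroquant
Title: Automated Quantification of Tubulointerstitial Kidney Fibrosis in
    Trichrome-Stained Photomicrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-capable image-analysis pipeline for measuring the percent
    fibrotic area in Masson's-trichrome-stained kidney sections. Stains are
    separated by Beer-Lambert optical-density colour deconvolution, normal
    renal structures (tubules, interstitium, optional manual regions) are
    segmented and excluded, the collagen (Methyl Blue) signal is thresholded
    with Otsu's method and a correction factor, and the fibrotic area fraction
    is reported per image with spreadsheet export. Includes a synthetic
    trichrome renal-tissue generator with ground-truth masks so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
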