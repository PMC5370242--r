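Package: mscarto
Title: 3D Molecular Cartography of Whole Organisms from Untargeted LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for building three-dimensional molecular
    maps of whole organisms (demonstrated on whole plants) from untargeted
    LC-MS/MS runs. Covers MS1 feature detection with chromatogram
    deconvolution, isotope removal and cross-sample alignment; MS/MS spectrum
    filtering, consensus clustering and molecular networking with modified
    cosine scoring; spectral-library matching; presence/absence ordination
    (binary Jaccard, PCoA) and tissue-overlap statistics; and export of
    per-feature ion-intensity tables onto a scanned surface mesh for
    rendering in 'ili. Includes a deterministic synthetic-plant simulator
    (mesh, sampling spots, metabolite panel, DDA runs and blanks) so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    igraph,
    generics,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
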