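Package: bbenrich
Title: Quantification of Balbiani Body Precursor Enrichment in 3-D Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the perinuclear enrichment of Balbiani body
    precursor components (dazl mRNA, Buc protein, DiOC6-stained organelles)
    around the centrosome in 3-D confocal stacks of early zebrafish oocytes.
    Implements the single-oocyte cleft analysis and the multi-cell zygotene
    nest analysis (threshold segmentation of nuclei, gamma-tubulin centrosome
    detection by 3-D connected components with a distance-transform center,
    sphere partition of the cytoplasm into centrosome-adjacent and
    centrosome-nonadjacent regions, background-normalized fold enrichment),
    block-scramble colocalization statistics (Pearson, Manders, PSF-sized
    block randomization), a synthetic ovary image generator with ground
    truth, and batch orchestration with group statistics and frequency
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    readxl,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
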