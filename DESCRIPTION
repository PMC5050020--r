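Package: quadfoci
Title: Quantification of G-Quadruplex Foci, Colocalization, Splicing and
    Binding from Patient-Derived Imaging and Densitometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying RNA G-quadruplex (BG4) immunofluorescence
    foci and hnRNP H colocalization in multichannel microscopy images, and
    for the downstream densitometry analyses that accompany such studies.
    Implements the BG4-Count trimmed-mean foci estimator (threshold the red
    channel, retain only staining overlapping DAPI, divide total stained
    area by the trimmed mean single-object area), nuclear/cytoplasmic
    colocalization event counting, per-experiment normalization to the
    average control cell with unpaired t-tests, percent-exon-inclusion
    splicing quantification with per-gene severity regression,
    sarkosyl-fractionation percent-insoluble and co-IP quantification, and
    one-site gel-shift binding-curve fitting. A synthetic-data generator
    with planted ground truth stands in for patient specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
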