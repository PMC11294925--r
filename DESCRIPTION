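Package: crypticniche
Title: Niche Breadth and Overlap of Cryptic Coral Species and Their Algal Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based identification of cryptic Pocillopora coral species
    (mtORF haplotype assignment with in-silico XhoI RFLP disambiguation of
    haplotype 1) and of their Symbiodiniaceae symbionts (ITS2 defining
    intragenomic variants and psbA non-coding region clades), together with
    the community statistics used to analyse their distribution across reef
    habitats: habitat-wise relative abundance with binomial likelihood-ratio
    tests, Bray-Curtis dissimilarity, principal coordinates analysis,
    distance-based redundancy analysis, PERMANOVA, Levins' niche breadth and
    Horn-Morisita niche overlap. Includes a synthetic-data generator that
    emulates a multi-site, multi-habitat reef sampling design so the whole
    pipeline is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
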