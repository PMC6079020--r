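Package: snowbiogeo
Title: Biogeography of Snow-Algal ITS2 Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully scripted pipeline for polar red-snow algal
    ITS2 amplicon surveys: paired-read merging and quality control, exact
    dereplication into phylotypes, de novo chimera screening, 98% greedy
    centroid OTU clustering, alignment-based taxonomic assignment against a
    user-supplied reference database, ITS2 secondary-structure hallmark
    validation with compensatory-base-change (CBC) species delimitation,
    endemic / Arctic-shared / entire-Arctic / bipolar biogeographic
    classification with read-share accounting, and permutation-based community
    statistics (PERMANOVA, Mantel, Bray-Curtis, UPGMA, Shannon-Wiener).
    Includes a ground-truth metacommunity read simulator so every stage can be
    validated against known truth without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    vegan,
    ape,
    igraph,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
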