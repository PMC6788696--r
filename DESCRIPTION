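Package: famcurate
Title: Gene-Family Curation, Clade Classification, Microsynteny and Promoter Element Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the bespoke computational
    stages of a large-scale gene-family phylogenomic survey: desk-scale
    homolog retrieval by local alignment with Karlin-Altschul E-values,
    iterative alignment-occupancy curation run to a fixed point, peptide
    signature based superclade and clade classification of homeodomain
    proteins, windowed microsynteny scoring with syntenic-proxy detection,
    and strand-aware promoter cis-element counting with overlap
    deduplication. A seeded synthetic-data generator plants known truth
    (clade labels, motif spans, fragments, syntenic blocks, promoter motif
    clusters) for every stage so each analysis can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
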