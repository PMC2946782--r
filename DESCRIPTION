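Package: ighclonal
Title: Clonal Set Identification in Immunoglobulin Heavy-Chain Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies clonally-related sequence sets in rearranged human
    immunoglobulin heavy-chain (IGH) repertoires. Reads aligner-partitioned
    sequences (V, N1, D, N2, J segments with germline gene calls), extracts
    the CDR3 junction using IMGT unique-numbering anchors, computes pairwise
    normalized edit distances augmented with IGHV/IGHJ germline mismatch
    penalties (NED_VJ), clusters by average-linkage agglomeration and cuts
    the dendrogram at an empirical threshold to emit clonal sets. Includes a
    synthetic V-D-J rearrangement and somatic-hypermutation simulator for
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
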