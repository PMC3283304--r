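Package: epsaligner
Title: Exact Pairwise Local Alignments Under an Error-Rate Threshold
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reports all maximal local alignments between two DNA sequences
    that have a minimal length and a maximal error rate under the edit
    distance model, excluding alignments that contain an epsilon-X-drop.
    The search combines lossless SWIFT q-gram filtration with a five-step
    exact verification (banded Waterman-Eggert core identification,
    X-drop core splitting, gapped X-drop extension, maximal-match
    cutting, and overlap removal). Includes a planted-alignment
    simulator, a coverage-based sensitivity benchmark, a brute-force
    reference enumerator, Karlin-Altschul E-value annotation, FASTA
    input and GFF output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    optparse,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
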