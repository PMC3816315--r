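Package: ovlcoarse
Title: Multilevel Overlap Graph Coarsening for Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pairwise overlaps between next-generation sequencing reads
    with a suffix-array k-mer seed search, q-gram filtering and banded overlap
    alignment; builds a weight-sorted overlap graph; iteratively coarsens the
    graph by Heavy Edge Matching under an edge-density constraint; and extracts
    read clusters at every coarsening level. Includes a simulated-metagenome
    generator with ground-truth labels and majority-vote evaluation of read
    binning, plus reduced-graph-traversal edge relabeling for locality.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
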