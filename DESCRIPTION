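Package: cvtreer
Title: Alignment-Free Whole-Genome Phylogeny from K-Peptide Composition Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-genome, alignment-free phylogenies from amino-acid
    proteomes using K-peptide composition vectors with Markov background
    subtraction, cosine dissimilarity and neighbor-joining, in the CVTree
    tradition. Includes proteome-level bootstrap resampling, a taxonomy
    reconciliation layer (rank collapsing with {m}/{m+n}/{k/m} labels,
    cross-K monophyly "convergence statistics", lineage modification rules),
    a synthetic proteome evolver for end-to-end validation, and readers and
    writers for proteome FASTA, lineage tables, Newick trees and square
    PHYLIP distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
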