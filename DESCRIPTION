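Package: glycoscan
Title: Comparative Glycogenomics of Giant-Virus Fibril Glycosylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to profile the conservation of fibril-glycosylation genes
    across giant-virus (Megavirinae) genomes. Implements a translated
    homology search (six-frame ORF extraction plus affine-gap Smith-Waterman
    alignment), a self-score-normalized conservation score and its N x M
    phyletic heatmap, delineation of glycogene clusters from ordered gene
    annotations (contiguity with gap bridging, and helicase/thioredoxin
    anchor genes), catalytic-residue conservation audits through multiple
    sequence alignments, completeness calls for nucleotide-sugar
    biosynthetic pathways, and GC-content comparison of glycogenes against
    core marker genes. A synthetic-genome simulator with implanted, diverged
    ortholog clusters provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    jsonlite,
    pheatmap,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
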