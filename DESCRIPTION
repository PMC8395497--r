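Package: ferriscan
Title: Classification and Regulatory Annotation of Invertebrate Ferritins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize invertebrate ferritin sequences against
    the human heavy-chain reference (HuHF): global pairwise alignment with
    EMBOSS-Needle-style identity and similarity, mapping of residues to
    conventional HuHF numbering, counting of amino acid replacements in the
    iron ion channel, ferroxidase di-iron center and ferrihydrite nucleation
    site, molecular weight and isoelectric point prediction, xRGG
    secretion-motif scanning with exact p-values, and a three-way
    classification into signal-peptide, conservative and atypical ferritins.
    Companion genomic tools annotate promoters (IUPAC motif scanning on both
    strands, HRE/HAS compound calls, CpG island detection) and predict
    iron-responsive element (IRE) stem-loops in 5' UTRs.  A descriptor-mining
    stage computes amino acid composition, CTD, pseudo amino acid composition
    and autocorrelation features, selects features with five unsupervised
    algorithms (Laplacian score, SPEC, MCFS, NDFS, UDFS), unites the top-k
    sets and projects them by PCA.  A synthetic-data generator provides
    planted-truth ferritin families, promoters and UTRs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    glmnet,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
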