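Package: ReadBERT
Title: Read-Level DNA Methylation Classification and Tumour Purity
    Estimation with a BERT-Style Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies individual bisulfite-sequencing reads into cell types
    from their DNA sequence and CpG methylation pattern using a BERT-style
    Transformer encoder (3-mer token, methylation and position embeddings;
    masked-language-model pre-training with neighbour-expanded masking;
    fine-tuned cell-type classifier with a DMR embedding), and turns per-read
    posterior probabilities into tumour-purity and cell-type-fraction
    estimates by grid-search maximum likelihood, with skewness-based
    estimation adjustment and Fisher-information precision reporting. Ships a
    beta-binomial read-level methylome simulator (region-level and
    CpG-specific scenarios, pseudo-bulk mixing) used as the evaluation bench,
    and a two-state hidden-Markov-model baseline read classifier.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
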