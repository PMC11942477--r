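Package: rnaduet
Title: Dual-Modality Sequence and Structure-Vision Modelling for RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling RNA with two coupled representations: a
    24-channel structural "vision" feature stack computed directly from the
    raw sequence (Nussinov-style maximum-matching maps, pairing-ambiguity and
    A-U availability counts, a Gaussian-decayed stacking propensity matrix,
    positional and one-hot distance maps, and Kronecker base-identity contact
    channels) and an overlapping k-mer token stream.  A BERT-style sequence
    encoder, a hierarchical shifted-window vision encoder, a self-/cross-
    attention fusion block and two downstream heads (sequence classification
    and a U-Net secondary-structure head) are provided as a compact
    CPU-trainable implementation, together with base-pair evaluation metrics
    (PPV, sensitivity, F1, MCC, ACC, AUROC, AUPRC), readers and writers for
    FASTA, dot-bracket, CT and BPSEQ, and seeded generators of synthetic
    sequences, nested structures and planted-motif datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
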