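Package: bindscreen
Title: Sequence-Based Virtual Screening with Cross-Attention over Protein
    Language Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-free (sequence-based) virtual screening. Ligands are
    parsed from SMILES into featurized molecular graphs whose atoms act as
    attention tokens over frozen per-residue protein language model latents
    drawn from several encoder depths. The network interleaves dynamic-attention
    graph convolutions with cross-attention graph blocks, pools with a learnable
    commutative monoid (or sum/mean), and predicts four binding affinities
    (pKi, pKd, pIC50, pEC50) plus a temperature-scaled, clipped binder-vs-decoy
    classifier logit. Includes decoy sampling, the masked Huber + binary
    cross-entropy multi-objective loss, AdamW with cosine decay, a
    homology-aware zero-shot train/test filter, forward and reverse screening
    drivers, early-recognition metrics (enrichment factor, success rate,
    BEDROC, AUROC), and a synthetic BindingDB-like data generator with a
    planted, recoverable binding rule.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nnet
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
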