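Package: nichesig
Title: Environmental Niche Signatures in Prokaryotic Proteome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies signatures of the environmental niche
    (domain of life, halophilicity, thermophilicity) carried by prokaryotic
    proteome sequences. Computes per-protein physico-chemical descriptors
    (amino-acid composition, amino-acid index scale means, isoelectric point,
    protein length, residue-class frequency ratios) and averages them to
    proteome-level feature vectors; reduces feature redundancy by rank
    correlation clustering (UPGMA on 1 - |Spearman rho|); evaluates supervised
    classifiers (random forest and RBF support vector machine adapters) with a
    repeated stratified split protocol, ROC/AUC, and permutation controls; and
    ranks features by classifier-agnostic permutation importance. Includes a
    synthetic proteome generator with planted, tunable compositional
    signatures and known ground truth so the full pipeline is testable
    without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    ranger,
    seqinr,
    stats,
    utils
Suggests:
    ape,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
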