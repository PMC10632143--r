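Package: microclone
Title: Clonal Deconvolution and Mutagenesis Analysis of Epidermal Microbiopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing somatic mosaicism in laser-capture
    microdissected epidermal microbiopsies. Implements post-calling
    genotyping and filtering of candidate somatic mutations (exact-binomial
    germline filter, beta-binomial overdispersion artifact filter,
    double-base-substitution merging), Dirichlet-process clustering of
    mutations by their variant-allele-fraction profiles across microbiopsies,
    clone phylogeny reconstruction by the statistical pigeonhole principle,
    supervised mutational-signature exposure attribution including a
    psoralen/PUVA TpA signature, transcription- and replication-strand
    asymmetry analyses, linear mixed-effects models of clone mutation
    burdens, and per-gene mutated-cell-fraction summaries. A synthetic
    cohort generator with full ground truth makes every stage testable
    without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ape,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
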