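Package: exomibe
Title: Derivation and Analysis of External Microbiomes of Micrometazoans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs external (cuticle-adherent) microbiomes of
    micrometazoans such as nematodes and tardigrades from paired
    washed/unwashed single-specimen metabarcoding samples, by per-replicate
    averaging of individuals and subtraction of internal (gut) from unwashed
    ASV abundances with negative clipping. Provides the surrounding
    community-ecology toolkit: target-domain and host-read filtering,
    negative-control subtraction, low-depth sample discard, Hill-number
    diversity profiles and Faith's phylogenetic diversity, Bray-Curtis
    dissimilarity, sequential-sum-of-squares PERMANOVA with permutation
    p-values, pairwise contrasts, principal coordinates analysis,
    multivariate dispersion testing, and a synthetic study generator that
    emulates a stream microbial-mat study design with ground truth for
    parameter-recovery assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
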