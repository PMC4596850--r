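Package: venomtx
Title: Venom-Gland EST Transcriptome Analysis and Toxin Precursor Annotation
Version: 0.1.0
Authors@R: person("venomtx", "maintainers", email = "venomtx@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing venom-gland expressed sequence tag (EST)
    libraries of disulfide-rich peptide toxins, modelled on fishing-spider
    (Dolomedes) venom transcriptomes. Provides EST cleaning and
    identity-based clustering with composition and cluster-size statistics;
    toxin precursor parsing into signal peptide, propeptide (Processing
    Quadruplet Motif cleavage) and mature peptide with C-terminal amidation
    processing; cysteine-pattern extraction, notation parsing and
    canonicalization into spacer-free skeletons with PSM/ESM motif
    detection; theoretical peptide mass and isoelectric-point calculation
    with closest matching against observed MALDI-TOF mass lists; pairwise
    global alignment distances, neighbor-joining trees with bootstrap
    support, and cross-species family classification. A seeded synthetic
    EST library generator with full ground truth makes every stage
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
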