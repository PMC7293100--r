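Package: introscan
Title: Detecting, Dating and Characterizing Ancient Introgression from
    Phased Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for ancient admixture between a donor species and
    one lineage of a recipient species from phased whole-genome haplotypes.
    Implements window-based divergence and introgression statistics (dXY,
    Weir-Cockerham FST, Patterson's D and fD, RND_min, topology weighting on
    neighbor-joining window trees), reference-free detection of archaic
    introgressed tracts with a Poisson hidden Markov model on private-variant
    counts, haplotype-copying local-ancestry painting, delineation of
    reproductive-isolation islands with a three-state HMM on the FST/Fintro
    ratio with FDR control, admixture dating from introgressed tract lengths
    and from the archaic HMM transition parameter, and conditioned (joint)
    site frequency spectra. A tract-level haplotype simulator with ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
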