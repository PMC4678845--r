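Package: bsamplicon
Title: Simulation and Analysis of Bisulfite Amplicon Sequencing with
    Lesion-Bypass Polymerases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse targeted (amplicon) bisulfite
    sequencing experiments in which the polymerase matters. The simulator
    models the bisulfite reaction at single-molecule resolution -- sulfonation
    of unmethylated cytosines to the 5,6-dihydrouridine-6-sulfonate (dhU6S)
    intermediate, condition-dependent desulphonation to uracil, 5mC
    protection, and collateral DNA damage -- followed by primer extension and
    PCR under polymerase profiles that encode uracil/dhU6S/lesion bypass,
    homopolymer stalling, extension-time effects and per-cycle
    misincorporation (a Taq-like profile, an engineered lesion-bypass
    profile, and blends of the two). The analysis side re-implements the
    standard amplicon bisulfite workflow: in-silico converted references,
    bisulfite-aware banded alignment, pileup, per-CpG methylation fractions,
    the non-CpG conversion-efficiency statistic, and substitution error rates
    with C-to-T events excluded, including per-PCR-cycle rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
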