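Package: hapmec
Title: Reliability of Minimum Error Correction Haplotype Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when the Minimum Error Correction (MEC)
    objective for diploid haplotype assembly recovers the true haplotype
    and when it provably fails. Implements the fragment-matrix model of
    sequencing reads over bi-allelic SNPs, the extended Hamming distance
    and the MEC objective, the majority-error failure witness, and the
    analytic reliability probability P{c-MEC} under constant,
    quasi-uniform and Poisson coverage. Includes a synthetic diploid
    read simulator with bi-substitution errors, exact and heuristic MEC
    assemblers, switch-error and block-length evaluation metrics,
    sequencing-device comparison via the Lander-Waterman equation, and
    reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
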