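Package: zimmbragg
Title: Finite-Size Analysis of the Zimm-Bragg Helix-Coil Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact transfer-matrix thermodynamics of the Zimm-Bragg
    helix-coil model for chains of any length, in both the {s, sigma}
    (propagation/cooperativity) and the Potts-like {W, Q}
    (bond-weight/phase-space-volume) parametrizations. Provides the exact
    finite-chain partition function evaluated stably in log space, its
    infinite-chain, long-chain and single-sequence (zipper)
    approximations with their validity windows measured against the
    correlation length, the corrected helicity degree, inflection-point
    melting analysis (transition point, interval, reduced melting
    temperature), size-scaling scans, brute-force enumeration oracles for
    small chains, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
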