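Package: dhcross
Title: Family-Size Design and Paternity Testing for Inter-Pollination
    Hybrid Breeding
Version: 0.1.0
Authors@R: person("dhcross", "maintainers", email = "dhcross@example.org",
    role = c("aut", "cre"))
Description: Toolkit for hybrid breeding schemes in which a group of
    genotyped inbred (doubled haploid) lines is inter-pollinated at random
    and elite F1 individuals are traced back to their paternal line by
    marker-based paternity testing. Provides exact combinatorial planning
    of F1 family sizes via Stirling numbers of the second kind (the
    occupancy probability Q(n, k, m), computed in exact big-integer
    arithmetic), SSR marker panel handling with diversity and exclusion
    statistics (Ho, He, PIC, non-exclusion probability), likelihood-ratio
    (LOD) paternity assignment with simulation-calibrated confidence
    thresholds, reciprocal-cross detection, and an end-to-end breeding
    simulator that validates the pipeline against the closed-form model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
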