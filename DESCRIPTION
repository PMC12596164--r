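Package: phaeopop
Title: Population-Level Analyses for a Host-Associated Phaeobacter Population
Version: 0.1.0
Authors@R:
    person("Jyllinge", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing a clonal, seasonally oscillating marine
    bacterial population sampled as cultured isolates over many years:
    a per-site Shannon-entropy statistic scoring the conservation of
    aligned protein products of biosynthetic and housekeeping genes,
    identity/ANI-based hierarchical clade assignment with temporal clade
    tracking, detection-limit-censored Log10 CFU abundance statistics
    (Kruskal-Wallis with Dunn/Bonferroni post hoc, bimodality occupancy,
    host-versus-seawater peak lag), and a forward-time simulator of a
    bottlenecked clonal population with founder clades and per-gene
    purifying constraint that generates synthetic isolate gene sets and
    censored abundance series for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
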