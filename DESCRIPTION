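Package: referralnet
Title: Organizational Referral Network Analysis for Health Service Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for organizational network analysis (ONA) of client
    referral networks among health service providers, motivated by studies of
    HIV and family planning service integration. Builds analyzable rosters
    from snowball nomination data, computes directed-network descriptives
    (density, degree, dyad census, reciprocity, Freeman centralization,
    attribute mixing matrices), fits exponential random graph models for
    dyadic-independent terms by maximum pseudolikelihood with Metropolis
    simulation for parameter-recovery checks, audits service-referral gaps,
    and produces workshop artifacts (organization directories, complementary
    service tables, sociogram exports). Ships deterministic synthetic
    fixture networks matching the published marginal constraints of two
    sub-city referral networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
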