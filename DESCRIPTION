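Package: voicesort
Title: Analysis of Voice Identity Sorting Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing free identity sorting tasks, in which listeners
    group naturally varying voice recordings into clusters by perceived speaker
    identity. Builds pairwise co-clustering response matrices, computes the three
    standard dependent measures per participant (number of clusters, telling-together
    and telling-apart scores), applies the vigilance-check and questionnaire-based
    participant exclusion rules with a retention ledger, runs the planned pairwise
    Mann-Whitney contrasts between talker- and accent-familiarity groups with a
    Bonferroni-adjusted alpha and rank effect size r, aggregates group-level mean
    co-occurrence matrices, and simulates complete synthetic cohorts so the whole
    pipeline can be exercised end to end without access to raw behavioural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
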