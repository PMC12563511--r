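Package: msptirr
Title: Multiscale Permutation Time Irreversibility Analysis of
    Neurophysiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinal-pattern analysis of neurophysiological recordings
    with an emphasis on time irreversibility. Implements amplitude
    permutations with a minimum-rank tie rule, permutation entropy,
    a permutation-based time irreversibility index (PTIRR), and their
    multiscale extensions (MsPE, MsPTIRR) via coarse-graining.
    Includes embedding-parameter selection (false nearest neighbors
    and the C-C delay method), zero-phase low-pass/notch/band-pass
    filtering with the standard delta-gamma band table, CTF-style
    sensor-to-region grouping, per-scale two-group statistics
    (t tests, two-factor ANOVA, significance-interval summaries),
    and a synthetic-cohort generator with a controllable
    irreversibility contrast for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
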