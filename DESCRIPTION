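Package: optovalence
Title: Optogenetic Place-Preference Analysis for Fly Stadium Arenas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optogenetic valence assays in which groups
    of walking flies are tracked in banded light-dark stadium arenas. Computes
    per-fly preference indices, light/dark speed ratios, and choice-zone
    transit statistics from head-coordinate tracks; estimates shared-control
    mean-difference effect sizes with bias-corrected and accelerated (BCa)
    bootstrap confidence intervals; aggregates replicates by fixed-effects
    inverse-variance meta-analysis and percent-of-control summaries; and
    regresses locomotor effect sizes against valence across driver-line
    screens. Includes an agent-based fly-walk simulator with independently
    tunable speed-modulation and boundary-turning valence mechanisms that
    provides ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    withr
Config/testthat/edition: 3
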