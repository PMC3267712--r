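Package: m60miner
Title: Profile-Based Discovery of M60-Like Extracellular Metallopeptidase Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering and characterising gluzincin
    metallopeptidase domains of the M60/enhancin type from protein sequence
    collections: iterative multiple-sequence-alignment curation with an internal
    progressive aligner, log-odds profile construction with shuffle-calibrated
    E-values, zincin (HEXXH) and gluzincin (HEXXHX(8,28)E) motif scanning with a
    PROSITE-style pattern subset, bit-score-difference subfamily partitioning,
    domain-architecture co-occurrence analysis, surface-targeting feature flags,
    and hypergeometric genotype-habitat association tests. A synthetic-proteome
    generator with full ground truth makes every stage verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
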