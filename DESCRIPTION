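Package: tetradose
Title: Allele-Dosage Penetrance Through Random Assembly of Tetrameric
    Channel Subunits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative model of how a gain-of-function channel-subunit
    allele can behave as a recessive, dosage-dependent mutation through
    random competition of redundant subunits for inclusion in tetrameric
    channel complexes.  Converts genotypes and expression-level
    interventions (overexpression transgenes, RNAi knockdown) into
    subunit-pool frequencies using exact rational arithmetic, computes the
    multinomial distribution of tetramer compositions analytically and by
    Monte Carlo, maps per-cell leaky-channel statistics to phenotype
    classes via a penetrance threshold, quantifies knockdown from qPCR
    cycle-threshold tables with the 2^-ddCt (Livak) method, and generates
    seeded synthetic datasets for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
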