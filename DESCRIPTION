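Package: nestwebs
Title: Succession and Local Stability of Ant Nest Symbiont Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing successional change in the arthropod symbiont
    communities of red wood ant nests and its consequences for food-web
    stability. Builds per-nest local food webs from functional-group abundance
    tables and a general trophic adjacency (with rarity filtering at an
    empirical quantile), samples signed interaction matrices, and assesses
    local asymptotic stability via the leading eigenvalue of the community
    matrix M = DA under four abundance-by-topology scenarios (observed or
    evened relative abundances crossed with observed or rewired topology).
    Includes community statistics (Pielou evenness, Bray-Curtis dissimilarity,
    PERMANOVA, PERMDISP, beta regression of evenness, rank-abundance
    summaries), stability regressions on nest age and community size, and a
    seeded synthetic-data generator emulating a survey of 51 nests in
    two age classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
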