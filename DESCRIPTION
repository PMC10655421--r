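Package: syncomdesign
Title: In-Silico Design of Synthetic Microbial Communities from
    Qualitative Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing synthetic microbial communities (SynComs)
    from qualitative genome-scale metabolic networks. Implements network
    expansion to compute individual and community metabolic potentials
    (scopes) from a seed growth medium, exact minimal-community selection
    for a set of target compounds with classification of essential and
    alternative symbionts across all optimal communities, reverse-ecology
    seed-set detection via source strongly-connected components with
    pairwise competition, complementarity, biosynthetic support and
    metabolic complementarity indices, presence/absence screening of a
    plant growth-promoting trait (PGPT) gene catalog, an end-to-end
    selection pipeline with iterative competitor exclusion, and a
    synthetic-instance generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
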