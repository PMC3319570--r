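Package: coexprofiler
Title: Geneset-Restricted Coexpression Profiling of Nuclear Receptors and
    Histone Methylation Modifiers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Profiles coexpression between nuclear receptors, histone
    methylation modifiers and endocrine-disruption phenotype genes across
    multiple biological settings (species, tissues, exposure experiments).
    Builds thresholded Pearson and partial correlation networks within a
    curated analysis geneset, tallies edges conserved across settings,
    scores phenotype genes for concordance with a gatekeeper coregulator
    set, and performs two-group differential expression with empirical-Bayes
    moderated t-statistics and Benjamini-Hochberg adjustment implemented
    from first principles. Includes a latent-factor synthetic-data
    generator with planted correlation modules, subgroup structure and
    fold changes, providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
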