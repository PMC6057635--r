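Package: cohortcat
Title: Cohort Metadata Cataloguing, Variable Search and Harmonization-Potential Tables
Version: 0.1.0
Authors@R:
    person("Catalogue", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A desk-scale cataloguing toolkit for population-based cohort
    studies. Provides a typed metadata model (study, subpopulation, data
    collection event, dataset, variable), a controlled-vocabulary variable
    classification taxonomy (18 domains, 135 subdomains), data-dictionary
    import/export in CSV dialects with a DDI-flavoured XML codebook export,
    a deterministic inverted-index search engine over studies and variables,
    harmonization-potential comparison tables, a multinomial naive Bayes
    term classifier, seeded synthetic-catalogue generators, and a command
    line interface wiring it all together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
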