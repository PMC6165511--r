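Package: rumenfiber
Title: Fiber Digestion Kinetics and Rumen Bacterial Community Association Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in-situ rumen fiber degradation experiments
    together with 16S rRNA gene taxon tables. Fits the negative exponential
    digestion model D = a + b(1 - exp(-c t)) per incubation unit, derives
    cellulose and hemicellulose fractions from proximate composition,
    computes lignin-marker apparent digestibility, aggregates lineage-typed
    taxon tables to any clade level, estimates Shannon, Chao1 and Good's
    coverage, censors taxa by Cook's influence distance against a kinetic
    response, and associates clades with digestion parameters through
    from-scratch NIPALS partial least squares with leave-one-out PRESS
    component selection and VIP scoring. A synthetic-data generator emulates
    a crossover feeding design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
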