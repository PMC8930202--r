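Package: relapsekit
Title: Genomic and Immune Dynamics of Paired Primary and Relapsed Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("relapsekit", "developers", email = "relapsekit@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing matched pre- and post-treatment tumor cohorts
    profiled by exome, copy-number and immune-repertoire sequencing: 96-channel
    trinucleotide mutation spectra with NMF signature extraction, catalog
    matching and non-negative exposure refitting; APOBEC tCw fold-enrichment
    classification; a control-referenced chromosomal-instability (CIN) score;
    tumor mutation burden, microsatellite-instability bands and MHC-I
    neoantigen filtering; clonal-cluster retention and mutation-sharing
    classes across serial samples; TCR-beta CDR3 repertoire diversity; and the
    exact nonparametric tests used to compare groups. A seeded synthetic-cohort
    generator emulates the statistical structure the analyses assume, so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
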