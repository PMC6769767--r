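Package: clonotherapy
Title: Intra-Tumour Heterogeneity-Aware In Silico Drug Prescription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evidence-based anticancer drug prioritization that accounts for
    intra-tumour heterogeneity (ITH). Ranks candidate drugs against a gene-drug
    evidence knowledge base, derives per-clone mutation complements from clonal
    phylogenies, contrasts bulk (predominant-clone) with ITH-aware druggability,
    designs combination regimens covering trunk and subclone populations, and
    stratifies patients a priori into responders and non-responders with
    Kaplan-Meier and log-rank survival comparison. Ships transcribed worked-case
    fixtures (an AML relapse genome and two multi-region NSCLC cases) and seeded
    synthetic-data generators so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
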