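Package: sfscreen
Title: Secondary-Findings Screening for Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens multi-sample exome cohorts for medically actionable
    secondary findings. Implements the automatic filter cascade over an
    ACMG SF v2.0-style actionable-gene list (gene restriction, autosomal
    recessive homozygote rule, tiered popmax allele-frequency filter, and
    retention by HGMD DM/DM? status, ClinVar pathogenic/likely-pathogenic
    assertions, or protein-truncating consequence), combines curator-supplied
    ACMG/AMP 2015 evidence codes with modified strength levels into a
    pathogenicity tier, assigns known-pathogenic (KP) / expected-pathogenic
    (EP) / others categories, and aggregates per-group and cohort-level
    reportable rates. Ships a synthetic-cohort generator with fully known
    ground truth so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
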