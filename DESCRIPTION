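Package: brca2hdr
Title: Functional Classification of BRCA2 DNA-Binding-Domain Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates homology-directed-repair (HDR) functional scores with
    95% credible intervals from replicate DR-GFP assay measurements of BRCA2
    DNA-binding-domain missense variants, calibrates the strength of that
    functional evidence against pathogenic and benign control standards via
    OddsPath, applies a tailored ACMG/AMP evidence-combination framework
    (PS3/BS3, population-frequency and in-silico codes, curated codes), and
    summarizes reclassification and concordance with external assertion sets.
    Includes seedable synthetic-data generators emulating the assay's
    data-generating process so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
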