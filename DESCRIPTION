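Package: iira
Title: ISNCSCI Classification and Item-Reduced Examination for Spinal Cord
    Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule engine for the International Standards for Neurological
    Classification of Spinal Cord Injury (ISNCSCI): per-side sensory and
    motor levels, neurological level of injury (NLI), sacral sparing,
    completeness and ASIA Impairment Scale (AIS) grade from a full
    134-item examination. Implements the S1-substitution shortcut that
    replaces the anorectal examination with S1 sensory and motor findings,
    and an adaptive item-reduction algorithm (IIRA) that determines NLI
    and AIS from a minimal, sequentially selected subset of exam items.
    Includes a seeded synthetic cohort generator with configurable
    level/grade mixtures, asymmetry and isolated sensory deficits, plus
    evaluation tools (AIS-grouping confusion tables, completeness error
    by NLI, upper-extremity weakness frequencies, item-count summaries)
    and worksheet CSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
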