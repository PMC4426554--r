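Package: ddicompare
Title: Comparing Drug-Drug Interaction Knowledge Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and comparing drug-drug interaction (DDI)
    knowledge sources. Drug names from heterogeneous interaction lists (an
    XML dialect carrying free-text interaction descriptions, a tabular
    record format carrying two-level severity annotations, and curated
    reference groups) are normalized to a common ingredient-level
    terminology: salt and ester forms collapse to their base ingredient and
    every discarded record is accounted for. On the normalized sets the
    package quantifies cross-source overlap, coverage of a curated
    reference list, per ATC-class-pair Jaccard similarity, and interaction
    detection rates on patient prescription lists (expanding
    multi-ingredient clinical drugs to ingredient pairs and excluding
    topical products). A synthetic-data generator plants known overlap,
    salt noise, and prescription pair frequencies so that every pipeline
    stage can be tested against an exact ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
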