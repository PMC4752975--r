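Package: ddicnn
Title: Drug-Drug Interaction Extraction with Convolutional Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts typed drug-drug interactions (mechanism, effect, advice,
    int) from sentences with annotated drug mentions. Implements the full
    pipeline: reading and writing DDIExtraction-2013-style XML corpora,
    candidate pair enumeration with drug blinding (drug1/drug2/drug0
    placeholders), rule-based negative-instance filtering, a convolutional
    sentence classifier over word and position embeddings trained with
    AdaDelta, challenge-style micro-averaged precision/recall/F evaluation,
    and a synthetic corpus generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
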