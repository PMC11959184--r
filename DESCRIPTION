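Package: silverlabels
Title: Silver-Standard Label Derivation and Keyphrase Validation for
    Unlabeled Scientific Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives ground-truth ("silver standard") keyphrase labels for
    unlabeled scientific documents by two non-ML routes: inheriting keywords
    from linked, already-labeled artifacts such as publications (artifact
    linkage), and concept recognition against pruned domain ontologies with
    document-frequency ranking. Machine-extracted keyphrases are validated
    against these derived labels by stemmed exact matching, with
    precision/recall/F-1 at top-N and an exhaustive hyperparameter grid
    search over the extractor settings. Includes a Porter stemmer, a
    deterministic fallback keyphrase extractor, descriptive label
    statistics, and a seeded synthetic-corpus generator with planted ground
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
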