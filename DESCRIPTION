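Package: notestructr
Title: Automatic Structuring of Free-Text Nursing Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns free nursing narratives into structured notes: segments
    text into sentences, classifies every sentence into a subject heading
    from a care-classification taxonomy, groups same-heading sentences into
    paragraphs, and iteratively merges semantically close paragraphs with an
    asymmetric, confidence-based similarity score. Also compares the learned
    heading representations (output-layer weight rows of the classifier)
    against the heading taxonomy via rank correlations, conflict-pair mining
    and hierarchical clustering, and ships a synthetic corpus generator so
    the whole pipeline is exercisable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    readr,
    withr,
    igraph,
    ape,
    Matrix,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
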