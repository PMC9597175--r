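Package: actd
Title: Anti-Cancer Target Discovery in Paired Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens gene-centric and metabolite-centric anti-cancer drug
    targets in paired cancer/healthy constraint-based metabolic models. Each
    candidate intervention is scored by fuzzy membership grades for cancer-cell
    mortality, healthy-cell viability and metabolic deviation (predicted side
    effects), aggregated by a mean-min operator into a hierarchical decision
    objective. Inner flux states come from flux balance analysis followed by a
    confidence-weighted uniform-flux-distribution quadratic program; the outer
    mixed-integer search over targets and modulation strengths uses a nested
    hybrid differential evolution algorithm. Includes readers and writers for a
    tabular model dialect, JSON and an SBML Level 3 FBC subset, gene-protein-
    reaction rule reduction, and generators for self-contained toy model pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
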