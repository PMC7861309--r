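Package: substkg
Title: Ingredient Substitution Ranking over a Food Knowledge Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks plausible ingredient substitutions over a food knowledge
    graph that joins recipes, an ingredient table, a food-class ontology and
    per-100 g nutrition records. Implements four pairwise ingredient
    similarity scores (two name-embedding cosines, a subclass-expanded recipe
    co-occurrence cosine, and a PPMI recipe-context cosine), combines them
    with the diet-improvement ingredient substitutability heuristic (DIISH)
    via a coefficient/power grid search, filters candidates by ontology
    super/subclass relations and dietary constraints, accounts recipe
    nutrition with common-unit gram conversion, and evaluates rankings with
    MAP, MRR and recall-rate-at-k against ground-truth substitution pairs.
    Ships a seeded synthetic knowledge-graph generator so every component is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
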