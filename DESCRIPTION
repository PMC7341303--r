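Package: focalnet
Title: Activity Budgets, Grooming Cliques, and Proximity-Based Social
    Networks from Focal-Animal Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of focal-animal sampling data
    from primate groups: per-individual activity budgets from instantaneous
    behavior samples, three-digit grooming-clique coding with mutual-grooming
    ratios, dyadic proximity indices assembled into weighted social networks
    with third-quartile filtering and eigenvector centrality, and the
    accompanying statistical battery (Mann-Whitney U, Kruskal-Wallis with
    Holm-corrected Dunn comparisons, Welch t, and a sex-label randomization
    test on centralities). Includes a synthetic colony generator that
    emulates instantaneous and one-zero sampling protocols so every stage of
    the pipeline can be exercised and calibrated without observational data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
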