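Package: proxnet
Title: Signed Social Networks from Nearest-Neighbor Scan Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers positive and negative social networks for groups of
    individually identified animals from scan-sampled locations or directly
    recorded nearest neighbors. Nearest-neighbor count matrices are tested
    cell-wise against a contingency-table null via standardized residuals;
    significant attractions and avoidances become signed weighted sociograms
    on which welfare-relevant node and group metrics (degree, betweenness,
    farness, cutpoints, blocks, density) are computed. Includes Mantel
    permutation tests for day-to-day network stability, 2-mode
    animal-by-facility affiliation networks, a cross-network comparison
    report, and a synthetic herd simulator with planted social structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
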