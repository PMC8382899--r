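Package: coaltrio
Title: Species-Tree Estimation and Error Theory for Three-Species Coalescent Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the simplest species-tree problem: three species, one
    sequence each, under the multispecies coalescent with the Jukes-Cantor
    mutation model and a molecular clock. Provides closed-form gene-tree and
    site-pattern probability machinery, an exact coalescent simulator of
    multilocus site-pattern data and alignments, four species-tree estimators
    (two-step majority vote, concatenation, independent-sites maximum
    likelihood, and full maximum likelihood under the coalescent via Gaussian
    quadrature), and normal-approximation theory predicting species-tree
    estimation error rates as a function of the number of loci and sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
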