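Package: motifnull
Title: Information-Content-Matched Null Models for DNA Sequence Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact samplers for DNA sequence motifs matched on information
    content (IC): the maximum-entropy distribution with a target mean IC and
    the truncated-uniform distribution over an IC interval, built on an
    integer-partition decomposition of column count vectors. Includes the
    informational Gini coefficient, parametric bootstrap percentiles of
    arbitrary motif statistics, GC-content-controlled sampling, and analytic,
    moment-matching and importance-sampling estimators of motif IC p-values
    with E-value conversion under a one-occurrence-per-sequence model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
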