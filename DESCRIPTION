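Package: axevol
Title: Axial Body-Plan Evolution on Time-Scaled Fossil Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how somitogenesis (presacral vertebral count),
    homeotic regionalization (cervical/dorsal count ratio), and post-patterning
    growth (unit length ratio) drive the evolution of body proportions on
    time-scaled fossil phylogenies. Provides randomization of ambiguous
    vertebral counts, consecutive-outgroup (Hedman-style) time-scaling of
    cladograms from stratigraphic ranges with hard node-age constraints,
    variable-rate Brownian-motion inference by reversible-jump MCMC over
    branch rate-shift configurations, standardized phylogenetic independent
    contrasts with through-origin regressions and ANCOVA, a pure-homeotic /
    pure-somitogenetic change decomposition, and synthetic-data generators
    (fossil birth-death trees, multi-rate and correlated Brownian traits,
    specimen tables) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
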