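Package: evostab
Title: Host-Aware Design of Evolutionarily Stable Genetic Feedback Controllers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A multi-scale simulator and design toolkit for synthetic gene
    circuits that must keep working while their host population evolves. A
    mechanistic single-cell resource-allocation model of bacterial gene
    expression couples any circuit or feedback controller to shared ribosomes
    and anabolites, so growth rate (and hence selection) emerges from circuit
    burden. Competing mutant strains, generated by promoter-level
    loss-of-function mutations, are integrated together with a shared
    substrate under a repeated 24-hour batch protocol. The package provides a
    library of feedback controller topologies (intra-circuit, growth-based,
    population-based; transcriptional and sRNA-mediated post-transcriptional
    actuation; multi-input combinations), evolutionary-longevity and
    bioproduction metrics, equal-output open-loop comparison, tri-objective
    NSGA-II controller design, and parametric robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
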