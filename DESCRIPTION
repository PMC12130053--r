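Package: befpart
Title: Additive Partitioning of Biodiversity Effects in Factorial
    Greenhouse Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diversity-ecosystem-function experiments that cross
    plant species richness with soil treatments. Constructs and validates
    balanced factorial designs (species pool x richness x treatment x
    replicate), computes plant functional traits (specific leaf area,
    specific root length, root-to-shoot ratio, total biomass) from
    individual-level morphometrics, and implements the Loreau-Hector
    additive partition of the net biodiversity effect into complementarity
    and selection components, with the additivity identity enforced as a
    numerical certificate. A synthetic-experiment generator with exported
    ground truth supports parameter-recovery testing, and grouped summaries
    with percentile-bootstrap intervals plus tidy model-ready exports close
    the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
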