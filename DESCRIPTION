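Package: palme
Title: Metabolism-and-Expression Modeling of Photoheterotrophic Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A metabolism-and-expression (ME) modeling toolkit for
    anaerobic-photoheterotrophic bacteria such as Rhodopseudomonas
    palustris. Builds joint metabolic and gene-expression networks with
    growth-coupled transcription, translation and enzyme-usage constraints
    (mu/kcat coupling), assigns turnover numbers by solvent-accessible
    surface area scaling, solves for the maximal feasible growth rate by
    bisection over linear-program feasibility with a parsimonious flux
    objective, and implements photoheterotroph-specific constraints:
    rubisco form I/II coexpression tied to carbon dioxide production,
    substrate-specific photosynthetic ATP caps, and the three nitrogenase
    isozymes (Mo, V, Fe) with ordered ATP costs. Ships a seeded synthetic
    toy network generator and analysis pipelines for growth profiling,
    electron-distribution sweeps through ferredoxin, nitrogenase
    temperature scans, and expression fold-change validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
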