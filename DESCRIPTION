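Package: rhizoseed
Title: Functional-Structural Simulation of Maize Seedling Root Systems
    and Seed Reserve Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale functional-structural plant model of maize and
    teosinte seedlings during the first 25 days after planting. Grows a
    segment-based three-dimensional root system (primary, seminal, nodal
    and lateral roots), couples it to a seed-carbohydrate and
    photosynthate carbon budget, and to a one-dimensional layered soil
    column with tipping-bucket water flow, nitrate convection-dispersion
    leaching, organic-matter nitrogen mineralization, Michaelis-Menten
    nitrate uptake, and Barber-Cushman radial-diffusion phosphorus
    uptake. Includes experiment runners for root-class nutrient
    accounting, environment grids, planting-density sweeps, composite
    phenotypes, and the optimization of seminal root number against seed
    carbohydrate reserves, plus generators for the synthetic phenotype
    and environment fixtures the experiments consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    xml2
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
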