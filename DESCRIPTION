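Package: astroabm
Title: Agent-Based Simulation of Astrocyte-Tumor Interactions in Brain Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid agent-based model of breast cancer brain metastases on a
    two-dimensional lattice. Tumor cells proliferate under distance-weighted
    influence from astrocytes, which switch irreversibly from an
    anti-metastatic to a pro-metastatic phenotype in response to local tumor
    density. Chemotherapy is modeled as a diffusible drug (alternating
    direction implicit solver) with gap-junction-mediated chemoprotection and
    a threshold-triggered 14-on/7-off dosing cycle. The package also provides
    boundary morphometrics (box-counting fractal dimension, lacunarity,
    eccentricity), six astrocyte seeding patterns with neutral-agent backfill,
    and an experiment harness with Sobol parameter sampling, partial rank
    correlation coefficients, regime stratification and group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
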