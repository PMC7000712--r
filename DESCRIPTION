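Package: ktau
Title: Kinetic Efficacy and Biased Agonism Analysis for GPCR Biosensor
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies G-protein-coupled receptor (GPCR) signaling
    kinetics from fluorescent-biosensor plate-reader time courses. Implements
    the mechanistic arrestin-recruitment model (association-exponential time
    course with observed rate rho_A*C + k_minus_N), the rise-and-fall
    biexponential model for second-messenger signals, and the curve-fitting
    workflows that extract the initial-rate efficacy parameter k-tau
    (Plateau x kobs at saturating agonist) and ligand affinity K_A. Kinetic
    biased agonism is quantified as ratios of reference-normalized k-tau
    values between pathways. Includes a seeded synthetic plate-reader data
    generator with known ground truth, plate quality-control statistics
    (delta-F/F normalization, replicate %CV, Z-prime, endpoint dose-response),
    delimited-text plate input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
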