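Package: bitesim
Title: Agent-Based Simulation of BiTE-Induced Immunological Synapse Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic agent-based simulators of immunological synapse (IS)
    formation induced by CD3/CD19 bispecific T cell engagers (BiTEs) at three
    nested scales: a base model (<= 1 h) coupling soluble-phase competing-ligand
    binding equilibrium, Smoluchowski cell-cell encounter kinetics, and
    two-dimensional ternary-bond adhesion probability; an in vitro model
    (<= 72 h) adding serial engagement, target lysis and CD19 antigen-escape
    evolution; and an in vivo model with organ compartments, lymphocyte
    trafficking, B-cell turnover and dosing regimens. Includes a synthetic
    cell-population generator, a grid-calibration utility for the adhesion
    sensitivity coefficient, YAML run configuration, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
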