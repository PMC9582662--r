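Package: electrotaxsim
Title: Self-Propelled Particle Simulation of Electrotactic Collective Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of directed (electrotactic) collective cell
    migration in a direct-current electric field, modelled on the anodal
    migration of human osteoblasts. Cells are soft disks with an intrinsic
    migration speed; their headings evolve by neighbour alignment with angular
    noise and by the net mechanical force they experience, which combines
    soft-core volume exclusion with a grid-sensed electric force. Positions
    follow overdamped dynamics on a periodic square domain. The package also
    implements the matching endpoint migration analysis used for cell-tracking
    centroid tables (displacement, full-quadrant migration angle, 10-degree
    angular sectors, speed scoring, anodal fraction, and the directionality
    order parameter), replicate-run experiments and parameter sweeps over the
    alignment radius, cell density, noise strength and field magnitude, plus a
    synthetic endpoint-table generator for testing the analysis layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
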