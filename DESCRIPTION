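Package: memflux
Title: Hindered Diffusion and Nernst-Planck Flux Modelling for Hemodialysis Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Irreversible-thermodynamics modelling of uremic-toxin transport across
    hemodialysis membranes. Computes the maximal linear dimension of a molecule from
    PDB coordinates, hindered effective diffusivities in cylindrical nanopores (Renkin
    hindrance polynomial) and across open-area hollow-fiber walls, and decomposes the
    transmembrane solute flux into diffusion, electromigration, pH, convection and
    ultrafiltration terms of the expanded Nernst-Planck equation, with parametric
    sweeps over applied potential, pH and membrane thickness and side-by-side
    membrane comparisons. Includes a synthetic-structure and synthetic-scenario
    generator with exactly known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
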