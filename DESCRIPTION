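Package: surfchannel
Title: Detecting Surface-Directed Ligand Diffusion Channels in MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for unbiased molecular dynamics simulations of
    substrate molecules diffusing around a protein. Reduces each substrate
    molecule to a per-frame centroid, applies an iterative nearest-unique-
    neighbour merge clustering with a distance cutoff to reveal the most
    populated positions in space (surface substrate channels), scores
    per-residue substrate population for structure colouring via B-factors,
    and detects and counts active-site arrivals against cofactor-anchored site
    definitions. Includes a synthetic trajectory generator with planted
    channels and scripted arrivals for validation, multi-model PDB and
    centroid-table I/O, and a pipeline orchestrator with a command-line
    wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
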