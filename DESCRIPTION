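Package: exoegress
Title: Product Egress Pathways, Ring Puckering and Binding Kinetics for
    Pocket-Shaped Exo-Hydrolases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale machinery for studying how a monosaccharide product
    leaves a deep pocket-shaped glycoside hydrolase active site. Provides a
    light structural model with PDB input/output, generators for certified
    synthetic pocket systems (a -1 binding well, a three-residue toll-like
    barrier, a lateral cavity and a solvent gate), a bead-level interaction
    energy and clash model, anisotropic network model normal modes with
    mode-directed backbone displacement, a multi-objective genetic search for
    clash-minimal exit paths, Metropolis Monte Carlo ligand migration,
    Cremer-Pople ring-puckering coordinates with canonical conformer
    classification, a classical well-tempered metadynamics engine validated
    on analytic surfaces, and competitive-inhibition and surface plasmon
    resonance affinity fitting with free-energy conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
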