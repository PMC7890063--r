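Package: pocketprofile
Title: Template-Based Active-Site Profiling and Kinetic Characterization
    of Terpene Synthases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-guided triage of terpene-synthase candidates.
    Extracts ligand-proximal (active-site) residues from template protein
    structures at a distance cutoff, merges pockets across templates into a
    unified active-site template, projects the template positions onto query
    sequences through global alignment, scores active-site identity, scans
    for the class I terpene-synthase aspartate-rich and NSE-triad motifs, and
    classifies candidates with sequence similarity networks and
    neighbor-joining trees. A companion kinetics module converts
    pyrophosphate-release assay time courses into Michaelis-Menten
    parameters (Km, kcat, catalytic efficiency) with standard-curve
    interpolation and initial-rate regression. Includes seeded generators
    for toy structures, homolog families with controlled active-site
    conservation, and simulated assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ape,
    igraph,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
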