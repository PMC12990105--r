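Package: epathcv
Title: Euclidean Path Collective Variables for Large Conformational
    Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing path collective variables
    that describe large conformational transitions such as GPCR
    activation.  Implements the Euclidean PATH variant (EPATH), defined
    on the plane spanned by the RMSDs to an inactive and an active
    reference structure, alongside the classic structure-based RPATH
    formulation.  Includes optimal (Kabsch) superposition RMSD, arched
    milestone construction in RMSD space, generation of PLUMED input
    blocks and weighted reference PDB files, parsing of COLVAR time
    series, reweighting of biased samples to one- and two-dimensional
    free-energy surfaces and free-energy-difference convergence traces,
    gromos conformational clustering with Shannon-entropy profiling
    along the path, and synthetic fixture generators (toy two-state
    structures, transition trajectories, biased Monte-Carlo samples on
    analytic double-well potentials).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
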