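Package: lcpaccess
Title: Substrate Access, Tunnels, Pockets and Binding Analysis for Latex
    Clearing Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric and energetic analysis of how a cis-1,4-polyisoprene
    chain reaches and binds the buried heme site of latex clearing protein
    (LcpK30). Provides grid-based tunnel detection with bottleneck, length,
    curvature and throughput statistics and average-link pathway clustering;
    alpha-sphere pocket detection with Monte-Carlo volume and hydrophobicity
    scoring; trajectory metrics (Kabsch superposition, RMSD, RMSF, cartesian
    PCA with porcupine modes, radial distribution functions, smoothing);
    an idealized cis-1,4-polyisoprene builder with double-bond numbering and
    the oxidative cleavage-product rule; ligand contact-fraction profiles,
    extended/folded conformation classification, near-attack-conformation
    cleavage-site profiling, and linear interaction energy decomposition.
    Includes seed-deterministic synthetic structure and trajectory generators
    with planted, analytically known properties for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
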