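Package: wrapkit
Title: Quantitative Analysis of DNA Wrapping by Tetrameric Bacterial Histones
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the structural and biophysical analysis of histone-DNA
    wrapping, developed around face-to-face (FtF) bacterial histone tetramers
    such as HLp from Leptospira perolatii. Provides structure and trajectory
    input/output with crystallographic symmetry expansion, idealized B-DNA
    model building and assembly of wrapping/bridging protein-DNA starting
    models, heavy-atom contact and binding-site analytics for molecular
    dynamics trajectories (binding fluctuation, moiety decomposition,
    hydrogen-bond occupancy), geometric descriptors (superposition, DNA
    backbone RMSD, tetramer planarity, helix crossing angle, wrap coverage,
    free-energy landscapes), steered-unwrapping post-processing (work
    profiles, barrier detection, release order, per-residue energy
    decomposition), quantitation of supporting assays (molecular masses,
    Shine-Dalgarno scanning, nuclease-ladder densitometry, tethered-particle
    logistic fits, binding isotherms), and deterministic synthetic-data
    generators with serialized ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
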