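Package: qti
Title: Quantitative Transient-State Imaging: Flow-Aware EPG Simulation,
    Sequence Design, Subspace Reconstruction and Bayesian Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative transient-state magnetic resonance
    imaging. Simulates transient-state magnetization with the Extended
    Phase Graph (EPG) formalism including a plug-flow washout operator for
    through-plane flow; optimizes flip-angle ramp acquisitions by Bayesian
    experimental design combining a Fisher-information utility with
    tissue-contrast terms; generates digital phantoms, variable-density
    spiral trajectories with golden-angle rotation, coil sensitivities and
    simulated undersampled multi-coil k-space; reconstructs time-resolved
    images via a temporal subspace and ADMM with local low-rank
    regularization; and infers per-voxel proton density, T1 and T2 with
    uncertainty by Markov chain Monte Carlo sampling, alongside
    dictionary-matching and least-squares baselines and angiographic
    maximum-intensity projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
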