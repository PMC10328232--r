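Package: ieegloc
Title: Anatomical Localization of Implanted Intracranial EEG Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular toolkit for localizing implanted intracranial EEG
    (sEEG depth and ECoG grid/strip) electrode contacts relative to brain
    anatomy in the patient's native space. Given a labelled parcellation
    volume, pial and white-matter surface meshes, a label lookup table and
    manually picked contact coordinates, it provides probabilistic region
    assignment from an expanding cylinder around each contact (electrode
    labelling algorithm), volumetric five-way tissue classification against
    watertight per-region enclosing volumes (electrode volume labelling),
    brain-shift correction that snaps surface arrays onto a smoothed pial
    surface by deterministic energy minimization, anatomical distance and
    angle measurements, oblique reslicing along depth-electrode
    trajectories, per-contact visual reports, and iEEG-BIDS electrode
    export. A synthetic labelled head phantom with analytic ground truth
    makes every stage testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    Matrix,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
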