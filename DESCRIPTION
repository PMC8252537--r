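Package: sysphantom
Title: Quantitative Analysis of the ISMRM/NIST MRI System Phantom
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis suite for the ISMRM/NIST MRI system phantom: geometric
    distortion and image uniformity from the 57-sphere fiducial lattice
    (cross-correlation sphere localization and generalized Procrustes
    similarity fitting), T1 relaxometry by inversion recovery and variable
    flip angle, T2 relaxometry by spin echo with noise-floor handling, proton
    density with local background normalization, SNR by the two-acquisition
    difference method, resolution-inset point-spread-function estimation
    against analytically synthesized images, and NEMA wedge slice-profile
    measurement. A digital-reference-object simulator renders synthetic
    phantom image series under the stated signal models with geometric
    distortion, receive-bias fields, and Rician noise, so every analysis
    stage is testable without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'geometry.R'
    'simulate.R'
    'fiducial.R'
    'io.R'
    'relaxometry.R'
    'pd_snr.R'
    'resolution.R'
    'slice_profile.R'
    'sysphantom-package.R'
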