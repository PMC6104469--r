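Package: dipolegrid
Title: Point-Charge Dipole Moments, Charge-Partitioned 3D Descriptors and
    Random-Forest Prediction of DFT Dipole Moments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes molecular dipole moments from per-atom partial
    charges treated as point charges at the nuclei of a given 3D
    structure, for any attached charge scheme (a built-in PEOE/Gasteiger
    assigner or externally supplied NBO-style charges).  From these it
    derives charge-sign-partitioned radial-distribution-function (RDF)
    descriptors, charge/mass projections binned along the dipole axis
    (PchmDM), and a MACCS fingerprint interface, and assembles them into
    fixed-layout feature vectors.  A random-forest regression workflow
    (out-of-bag mtry tuning, permutation-importance feature selection,
    MAE/RMSE/R2 evaluation and y-randomization) predicts DFT-quality
    dipole magnitudes from those features.  A synthetic molecule
    generator provides charged point-charge clouds for testing and
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
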