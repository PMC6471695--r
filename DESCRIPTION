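Package: cryores
Title: Resolution Validation of Cryo-EM Density Maps by Volumetric Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates resolution-labelled three-dimensional electron density
    volumes from atomic models, prepares them for volumetric neural networks
    (normalisation, central crop or zero-pad, masking, power-of-two padding,
    16x16x16 patch extraction with empty-cube removal, reproducible dataset
    splits), trains three classifier architectures (a dense network and a 3D
    convolutional network for global high/medium/low resolution classes, and
    a 3D U-Net for voxel-wise classification into ten resolution bins), and
    evaluates predictions with multi-class diagnostics: confusion matrices,
    combined agreement, per-class sensitivity/specificity/PPV/NPV,
    voxel-wise categorical accuracy, resolution-boundary scans and
    cross-model evaluation grids. Reads and writes MRC2014 volumes and PDB
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'benchmark-data.R'
    'evaluate.R'
    'io-mrc.R'
    'io-pdb.R'
    'network-spec.R'
    'network-train.R'
    'phantom.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
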