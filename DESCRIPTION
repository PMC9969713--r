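Package: pscplant
Title: Dual RGB-D Reconstruction and Trait Evaluation of Potted Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs colored three-dimensional point-cloud models of
    potted plants from a pair of opposed, mirror-symmetric RGB-D depth
    cameras. Implements pinhole depth back-projection, depth-to-color
    registration, axis-aligned region-of-interest (PassThrough) cropping,
    two-sided statistical outlier removal with coordinate-descent parameter
    selection, a closed-form point-cloud spatial-coordinate (PSC) fusion of
    the two opposed views, bounding-box trait extraction (height, width,
    length, volume), and accuracy evaluation against manual measurements.
    A virtual dual-camera rig renders procedural plant scenes with a
    Kinect-like depth noise model for ground-truth testing, and a
    point-to-point ICP registration baseline supports speed and accuracy
    comparisons on synthetic turntable captures.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RANN,
    png,
    yaml,
    jsonlite,
    withr
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'pscplant-package.R'
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'filtering.R'
    'fusion.R'
    'traits.R'
    'evaluate.R'
    'tables.R'
    'synthetic.R'
    'icp.R'
    'compare.R'
    'io-png.R'
    'io-cloud.R'
    'pipeline.R'
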