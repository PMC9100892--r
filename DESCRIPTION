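Package: RootBallPheno
Title: Non-Destructive Root Phenotyping of Plug Seedling Root Balls from
    Multi-View RGB-D Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures and predicts root-system phenotypes of plug seedlings
    (e.g. pumpkin rootstock) without washing the root ball. Four colour+depth
    views taken against a high-texture fiducial background are registered with
    a Harris/ANMS/RANSAC homography chain and composited into a single surface
    panorama; surface roots are segmented with a multi-scale Hessian (Frangi)
    vesselness filter after edge-based background removal and homomorphic
    illumination correction; pixel metrics are calibrated from the depth point
    cloud; and average root diameter, surface areas, encapsulation, and
    total-root surface area, length and volume are computed from the
    segmentation via allometric linear models. A synthetic scene generator
    with full analytic ground truth makes every stage testable without a
    camera.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Visualization, Segmentation, Phenotype
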