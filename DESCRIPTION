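Package: fiberarch
Title: Quantification of White-Matter Fiber Architecture in 3D Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the local organization of axonal fibers in
    three-dimensional light microscopy volumes of labeled white matter.
    Per-voxel fiber orientations are estimated by 3D structure tensor
    analysis, aggregated into discrete orientation distribution functions
    (ODFs) over a dense spherical sampling per analysis cube, and summarized
    by generalized fractional anisotropy and separation-constrained ODF
    peaks. The spatial arrangement of fibers is characterized by the 3D
    autocorrelation of the local orientation (dyadic) tensor field,
    exponential-decay correlation lengths along fiber-frame axes, and a
    spectral screen for laminar periodicity in transverse autocorrelation
    profiles. A synthetic tubular-fiber phantom generator with voxel-level
    ground truth (meshwork, laminar/orthogonal, and bundled motifs) supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'fiberarch-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'acf.R'
    'laminar.R'
    'maps_io.R'
    'sphere.R'
    'odf.R'
    'orientation.R'
    'phantom.R'
    'pipeline.R'
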