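Package: registrack
Title: Registration-Based Tracking of Transient Objects in 3D Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tracks transient fluorescent objects (for example short-lived
    mitotic reporters) in unregistered 3D time-lapse microscopy by merging
    registration and identity management into a single random-sampling
    procedure. Candidate frame-to-frame transformations are proposed from the
    data itself (all pairwise translations, then rigid transforms fitted to
    sampled triangular constellations of likely inliers), ranked with an
    epsilon-capped nearest-neighbour least-squares cost, and used to propagate
    object identifiers into a binary objects-by-frames Life Matrix. Includes a
    volumetric pre-processing front end (wavelet noise estimation and routing,
    region-of-interest isolation, annealing thresholding, difference-of-
    Gaussians centroid detection), post-tracking outlier filters, a surrogate
    point-set generator with ground-truth transformations for validation, and
    a lag consistency test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    vegan
Config/testthat/edition: 3
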