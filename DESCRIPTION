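Package: limbtrack
Title: Landmark-Based 2D/3D Registration for Articulated Skeletal Pose
    Estimation from Single Cone-Beam Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the rigid and articulated pose of a limb-like
    skeletal object from a single cone-beam X-ray radiograph, given a 3D
    reference volume.  The package covers the full chain: bone segmentation
    (Otsu threshold, morphological closing, 6-connected labeling) and
    principal-axis bone frames; automatic 3D reference landmark extraction by
    a shortest-coordinate-variance greedy scheme over bone voxels or
    difference-of-Gaussians scale-space keypoints; simulation of articulated
    motion by log-Euclidean polyaffine fusion of per-bone rotations with
    Gaussian weight maps and tricubic inverse warping; ray-driven cone-beam
    radiograph simulation with Poisson noise; per-landmark voting vector
    fields with RANSAC-style hypothesis voting and inverse-covariance
    weights; a compact residual convolutional network for 2D landmark
    detection; and staged weighted least-squares reconstruction of the
    5+N pose parameters.  A built-in two-bone limb phantom generator with
    known segments, joints and ground-truth poses supports fully synthetic
    end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
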