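---
title: "Articulated 2D/3D registration with limbtrack: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Articulated 2D/3D registration with limbtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Skeletal kinematics of small animals can be recovered from single-view
X-ray fluoroscopy if the 3D pose of each bone can be registered to a 3D
reference volume (typically a CT scan of the same limb).  `limbtrack`
implements a landmark-based route: well-spread 3D reference landmarks
are extracted automatically from the segmented bones, their 2D
counterparts are located in each radiograph (either by encoding and
voting ground-truth vector fields in simulation, or by a convolutional
detector), and the pose is reconstructed by minimizing the weighted
reprojection error.  Because real fluoroscopy with known ground truth is
hard to come by, the package also contains the full simulation chain —
articulated deformation of the reference volume, cone-beam projection,
Poisson noise — plus a synthetic two-bone limb phantom, so the entire
method can be exercised and validated end to end with exact ground
truth.

# Geometry and pose parameterization

A calibrated cone-beam system is described by the source-to-isocenter
and source-to-detector distances (SOD, SDD), a detector grid with its
pixel pitch, and an integer binning factor $b$.  The magnification at
the isocenter is SDD/SOD.  The object pose comprises translations
$(x^o, y^o, z^o)$ along the horizontal, vertical and projection axes,
and rotations $\theta^o$ (about the projection axis), $\phi^o$ (the
projection/gantry angle, about the vertical axis) and the pitch
$\eta^o$ (about the horizontal axis).  Because the parent joint's pitch
plays the same role as $\eta^o$, the rigid pitch is *not* a free
parameter of the registration vector; with $N$ articulated joints the
vector is
$$\tau = \{x^o, y^o, z^o, \theta^o, \phi^o, \eta_{j_1},\dots,\eta_{j_N}\},$$
$5+N$ parameters in total.

The literature rarely states which rotation attaches to which axis
beyond "$\phi^o$ is the projection angle"; we fix the convention
$R = R_y(\phi)\,R_z(\theta)\,R_x(\eta)$ with $x$ horizontal (detector
rows), $y$ vertical, $z$ source-to-detector.  All public interfaces use
degrees; radians are internal.

# Bone segmentation and frames

Segmentation is the classical morphological pipeline: Otsu threshold
(256-bin histogram over the data range, ties toward the lower cut),
removal of 6-connected components below a voxel count, morphological
closing with a cubic structuring element, and 6-connected labeling with
labels sorted by size.  At full CT resolution a closing window of
$25^3$ is appropriate; at the phantom's scale (bone radii of ~5 voxels,
joint gap of ~7) the default is $5^3$ — a window larger than the joint
gap would weld the two bones into one component.

Each bone's local frame comes from PCA of its unweighted voxel
coordinates: the largest-variance eigenvector is the longitudinal axis
$e_y$, the middle one the vertical axis $e_x$, and $e_z = e_x \times
e_y$ the transverse axis (the flexion/extension axis the joint pitches
rotate about).  The joint origin is the center of mass slid along
$e_y$ by $2\sqrt{\sigma_{\max}}$ — two standard deviations, the
semi-axis of an equivalent uniform rod.  Which end is "the joint" is a
sign choice a human would settle visually; `bone_frame()` exposes it as
`end_hint`, and the pipeline resolves it against the phantom's known
joint positions.

# 3D landmark selection

Landmarks must spread over the bone surface and keep apart, or their
2D projections collide.  The selection scheme is greedy: start from the
candidate farthest from the center of mass, then repeatedly take the
farthest candidate whose distance to *every* selected landmark is at
least $\lambda\, s_{\min}$.  Candidates are either surface voxels of
the bone ("bounding" landmarks) or volumetric difference-of-Gaussians
scale-space extrema ("SIFT-style" landmarks; positions only — the
selection scheme has no use for descriptors).

One subtlety: the PCA eigenvalue $\sigma_{\min}$ is a variance
(voxels$^2$) while the pairwise floor is a distance.  We compare
against $\lambda\sqrt{\sigma_{\min}}$ by default, which makes the
published $\lambda$ values (roughly 2–4) span a bone's minor radius
sensibly; `use_sqrt = FALSE` restores the literal product for
compatibility.  Ties in the distance-to-CoM ordering break toward the
lexicographically smallest coordinate, making selection deterministic
and invariant to candidate order.

# Polyaffine articulated motion

Joint motion is simulated by fusing per-bone rotations.  Each bone $t$
rotates by its pitch about its transverse axis through its joint
origin; the rotation's log-speed is $A_t = \log R_t$ with
$$\log R_t = \frac{\alpha_t}{2\sin\alpha_t}(R_t - R_t^\top),\qquad
\alpha_t = \angle R_t \in (0, \pi),$$
and fusion weights are Gaussian-diffused segment masks
$\omega_t = g(\sigma_f, k_f) * V_t$, normalized voxelwise.  One
sub-step of scale $S$ displaces a point by the weight-blended average
of the per-bone exact exponential steps (rotation by $\alpha_t/S$
about the bone origin), and $k$ compositions give the motion at time
$k/S$.

Two numerical points deserve attention:

* **Angle extraction.**  $\alpha = \arccos((\mathrm{tr}\,R - 1)/2)$ is
  exact algebra but numerically dead below $\sim 10^{-8}$ rad: the
  cosine rounds to 1.  We evaluate the same angle as
  $\mathrm{atan2}(\|w\|, (\mathrm{tr}\,R-1)/2)$ with $w$ the
  antisymmetric part's axis vector.  This matters in practice — a
  derivative-based pose solver probing $\eta$ around zero sees a flat
  cost under the arccos form and never moves.

* **Weight handling along the composition.**  Re-evaluating the
  fusion weights at each intermediate position (the Eulerian,
  stationary-velocity reading) is only meaningful while trajectories
  stay inside the truncated kernel support: a bone point swept beyond
  the reference support freezes mid-motion, and at articulations of
  $20^\circ$ and up this produces many-voxel round-trip errors.  The
  default therefore freezes each point's weights at its initial
  position (a material, Lagrangian reading): points deep inside one
  bone then move exactly rigidly for any rotation magnitude, the blend
  across the joint stays smooth, and the single-bone uniform-weight
  composition reproduces the rigid rotation to machine precision
  ($({\rm e}^{A/S})^S = {\rm e}^A$ exactly, step by step).
  `freeze_weights = FALSE` restores the re-sampling variant.

The inverse motion negates every angle; with shared frozen weights the
round trip is exact to machine precision, and volume warping maps each
target voxel back through the inverse composition before tricubic
interpolation.  Interpolation is local separable Lagrange tricubic on
the $4^3$ neighborhood: it reproduces per-axis cubic polynomials
exactly, passes through the samples, and needs no global solve.

Defaults: $S = 18$, and at full CT scale $\sigma_f = 13$, $k_f = 23$;
the phantom-scale pipeline uses $\sigma_f = 3$, $k_f = 9$, scaled to
its ~10x smaller bone radii.

# Radiograph simulation

The projector is ray-driven: for each binned detector pixel the
source-to-pixel ray is marched at 0.5-voxel steps with trilinear
sampling, scaled by the step length.  Binning happens *inside*
projection (one ray per binned pixel), matching the view of binning as
a geometry property.  Central chords through uniform boxes reproduce
analytic path lengths within 2%; a finer step buys little at these
scales.  Poisson noise follows the simulated-campaign recipe exactly:
the noiseless image is scaled so its maximum is $I_0$, then each pixel
is replaced by a Poisson draw.  Whether such noise should act on
attenuation line integrals or on transmission intensities is ambiguous
in the source material; the literal attenuation-domain reading is the
default.  The default campaign (the "training plan") enumerates a
$6\times5$ articulation grid, forty $\pm1.5^\circ$ intervals in
$(-30^\circ,30^\circ)\cup(150^\circ,210^\circ)$, 13 projections per
interval — 15,600 radiographs — with jittered SOD/SDD, translations of
$\pm180/\pm120/\pm180$ voxels, horizontal-axis rotations of
$\pm15^\circ$, and $I_0 = 2000\pm350$.

# 2D landmarks: vector fields, voting, and the detector network

Each landmark is encoded over its bone mask as a field of unit vectors
pointing at it.  Voting intersects sampled pixel-pair rays into
hypotheses, scores each by its angular-consistency inliers
($\cos \geq 0.99$), and summarizes the landmark as the score-weighted
hypothesis mean $\hat\mu$, the scalar covariance $\sigma$ (weighted
mean squared distance to $\hat\mu$) and the weight
$\omega = 1/(\sigma + \varepsilon)$ that later penalizes the
registration residuals.  Plain score-weighted averaging of *all*
hypotheses is biased by gross outlier intersections once a fraction of
the field is corrupted; the estimator therefore averages only
hypotheses within a consensus radius (3 px) of the best-scoring one —
standard RANSAC practice — which keeps the error below 1 px at 20%
corruption while remaining exact on clean fields.

The detector network is a ResNet-style encoder–decoder: a stride-2
stem, four stages of two-convolution basic blocks with depths
$[3,3,4,3]$ (the baseline $[2,2,2,2]$ deepened by $1,1,2,1$ blocks),
resolution bottoming at 1/8 with dilated later stages, and a decoder of
three upsample+convolution steps whose first skip connection is sourced
from encoder stage 3.  Heads emit $2K$ vector-field channels plus two
segmentation logits at full resolution.  The loss is masked smooth-L1
(Huber, $\delta = 1$) on the fields plus softmax cross entropy on the
segmentation; a subtractive cross-entropy convention appears in print
but would reward bad segmentation, so the sum is the default and the
sign is switchable.  The network is implemented as a small,
self-contained layer framework in base R (im2col convolutions through
BLAS, batch normalization, bilinear upsampling, Adam), verified against
numerical gradients.

Training protocol: the reference full-scale protocol (base rate
$10^{-5}$, halved each of the first five epochs, up to 600 epochs) is
available as `reference_train_protocol()`, but it is calibrated for
full-resolution GPU-scale training; at desk scale (64-px inputs, tens
of samples, tens of epochs) that rate cannot move a freshly initialized
network measurably, so the desk default uses a base rate of $10^{-3}$
(and the smoke experiments $2\times10^{-3}$ without decay).  One model
per (bone, landmark-type) is assumed, as in the four-model setup the
method was introduced with.

# Staged pose reconstruction

The estimate minimizes
$$\hat\tau = \arg\min_\tau \sum_{i=1}^{N}\sum_{k=1}^{K}
\omega_{ik}\left[(u^r_{ik}(\tau) - u^m_{ik})^2 +
(v^r_{ik}(\tau) - v^m_{ik})^2\right]$$
with the articulated forward model: polyaffine transformation of the
reference landmarks with fusion weights frozen at their reference
positions (matching exactly how the ground-truth 2D landmarks are
generated), followed by the rigid pose and the cone-beam projection.
A rigid kinematic-chain forward model is provided as an alternative.

The schedule follows the staged order — projection angle $\phi^o$
first, then the vertical coordinate $y^o$, then the three offsets, then
the joint pitches, then the orientations $\{\theta^o,\phi^o\}$ —
iterated until parameter updates or the cost change fall below
$10^{-8}$, each stage a bounded Levenberg–Marquardt solve with
numerical Jacobians, from an all-zero initialization.  Three
robustness devices were needed to make this reliable at the simulated
ranges, and all are visible in `registration_config()`:

* the $\phi$ stage begins with a coarse grid scan (acquisition angles
  cluster in two opposite ranges, and a local solve from $0^\circ$
  cannot cross to the $180^\circ$ basin); each candidate angle gets a
  quick in-plane translation fit so the scan is not blinded by unknown
  offsets, while the depth coordinate deliberately keeps its start
  value;
* a multi-start over the depth coordinate $z^o$ (the weakest-observed
  parameter from a single view), with early stop once the cost is
  essentially zero;
* a profiled 1-D depth search as a fallback: the depth/articulation
  valley is narrow and curved, and a Levenberg–Marquardt step pinned at
  a depth bound cannot slide along it, while the profiled cost over
  $z$ (all other parameters re-fitted) is smooth and unimodal in
  practice.

With fewer than 3 landmarks on some joint the rotation stages are
refused and a partial, translation-only estimate is returned; fewer
than 6 usable landmarks overall is an error.  Error summaries
(`evaluate_errors()`) report the median, type-7 quartiles,
1.5-IQR whiskers and outliers per parameter — the statistics behind
the usual boxplots.

# The phantom, and what passing tests do and do not show

The phantom is a deliberately simple stand-in for a dissected-limb CT:
two capsule bones with two condyle-like spherical bulges at their joint
ends (the bulges break the cylindrical symmetry that would otherwise
leave frame signs and keypoints ill-defined), meeting at a knee-like
junction, inside a soft-tissue ellipsoid, with seeded texture noise
clipped so the attenuation ordering background < soft tissue < bone
holds voxelwise by construction.  Defaults: $96^3$ voxels, bone
half-lengths 20/17, radii 5.5/4.5, joint gap 7, inter-bone angle
$30^\circ$, attenuations 0/0.25/1, noise sd 0.02.

What it shares with real data: elongated bones with distinct principal
axes, a two-bone joint with a blended deformation zone, realistic
projection geometry and Poisson statistics, landmark correspondence
maintained under articulation.  What it lacks: anatomical shape
variation, internal trabecular structure, muscle and overlapping soft
tissue, detector/source physics, scatter, and motion blur.
Consequently, passing the pose-recovery experiments demonstrates that
the *geometry, simulation and optimization machinery* is correct and
well-conditioned at realistic parameter ranges — not that the detector
network reaches sub-pixel accuracy on real fluoroscopy, which requires
full-scale training far beyond desk scale.

# Problem sizes used by the tests and the acceptance script

Reference phantom $96^3$; detector $576^2$ binned by 6 to $96^2$
images for rendered experiments; landmark sets of $K = 20$ per bone
(two bones, $\lambda = 1.4$ at phantom scale so that 20 landmarks
satisfy the pairwise floor — fewer landmarks measurably inflate the
depth and joint-angle errors); pose-recovery experiments use 50 random
poses drawn from
the full simulated training ranges with analytic (non-rendered)
observations; the network smoke experiments use twenty $64^2$ toy
samples for 30 epochs and a single-sample overfit for 200 epochs.
These sizes were chosen so the whole suite exercises every stage in a
few minutes on one CPU while staying in the regime where the method's
properties (exactness of the rotation limit, sub-pixel voting,
parameter recovery) are sharply testable.

# Known limitations

* The polyaffine inverse (negated angles) is exact only with shared
  frozen weights; warping quality degrades where trajectories cross
  steep weight gradients.
* Depth ($z^o$) from a single view is intrinsically weakly observable;
  with noisy observations its error is an order of magnitude larger
  than the in-plane translations, consistent with the magnification
  argument (a 2% depth error is sub-pixel at these geometries).
* The voting covariance is scalar, not a full 2x2 matrix; anisotropic
  hypothesis clouds are summarized by their mean squared radius.
* `acos`-free angle extraction notwithstanding, rotations within
  $10^{-6}$ deg of a half turn are rejected by the log branch.
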