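#' Rotation angle of an orthonormal matrix
#'
#' The angle whose cosine is `(tr(R) - 1) / 2`.  It is evaluated as
#' `atan2(sin, cos)` with the sine taken from the antisymmetric part of
#' `R` -- algebraically identical to the arccos form but numerically
#' stable for small angles (arccos of a cosine indistinguishable from 1
#' collapses below about 1e-8 rad, which would flatten derivative-based
#' optimization near zero articulation).  Errors when `R` is not
#' orthonormal (`max|R'R - I| > 1e-6`).
#'
#' @param R A 3x3 rotation matrix.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation_angle: input is not orthonormal")
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  atan2(sqrt(sum(w^2)), (sum(diag(R)) - 1) / 2)
}

# rotation axis (unit) and angle from the antisymmetric part
axis_angle <- function(R) {
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  s <- sqrt(sum(w^2))
  alpha <- atan2(s, (sum(diag(R)) - 1) / 2)
  list(axis = if (s > 0) w / s else c(0, 0, 1), alpha = alpha)
}

#' Matrix logarithm of a rotation
#'
#' The antisymmetric log-speed of a rotation:
#' `log(R) = alpha / (2 sin(alpha)) * (R - R')` for
#' `alpha` in `(0, pi)`, and the zero matrix at `alpha = 0`.  The branch
#' is undefined at a half turn; angles within `1e-6` of `pi` error.
#'
#' @param R A 3x3 rotation matrix with `det(R) = 1`.
#' @return A 3x3 antisymmetric matrix `L` with `expm(L) = R`.
#' @export
log_rotation <- function(R) {
  alpha <- rotation_angle(R)
  if (alpha < 1e-12) return(matrix(0, 3, 3))
  if (alpha > pi - 1e-6)
    stop("log_rotation: rotation angle at/near pi, log branch undefined")
  alpha / (2 * sin(alpha)) * (R - t(R))
}

#' Rotation about an axis (Rodrigues form)
#'
#' @param axis Length-3 direction (normalized internally).
#' @param angle Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Polyaffine fusion configuration
#'
#' @param S Fusion time scale: the number of 1/S sub-steps composed to
#'   reach the full transformation (integer `>= 1`).
#' @param sigma_f Standard deviation of the Gaussian used to diffuse
#'   each bone segment into its fusion weight map (voxels).
#' @param k_f Width of the (truncated) Gaussian kernel (voxels, odd,
#'   `>= 3`).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(S = 18L, sigma_f = 13, k_f = 23L) {
  stopifnot(S >= 1, sigma_f > 0, k_f >= 3, k_f %% 2 == 1)
  structure(list(S = as.integer(S), sigma_f = sigma_f, k_f = as.integer(k_f)),
            class = "fusion_config")
}

#' Gaussian fusion weight maps
#'
#' Per-bone raw weight = truncated Gaussian kernel (sd `sigma_f`, width
#' `k_f`) convolved with the binary segment mask; normalized weights
#' divide by the voxelwise sum across bones wherever that sum exceeds
#' `eps` (elsewhere the voxel belongs to the identity region and no
#' transformation is applied).
#'
#' @param labels A [label_volume()].
#' @param bones Integer vector of bone labels.
#' @param config A [fusion_config()].
#' @param eps Support threshold on the raw weight sum.
#' @return An object of class `fusion_weights`: `raw` and `norm` lists
#'   of arrays (one per bone), logical `support` array, `bones`, `eps`.
#' @export
fusion_weights <- function(labels, bones, config = fusion_config(),
                           eps = 1e-6) {
  stopifnot(length(bones) >= 1)
  r <- (config$k_f - 1L) %/% 2L
  raw <- lapply(bones, function(b)
    smooth3(array(as.numeric(labels$data == b), vol_dims(labels)),
            config$sigma_f, radius = r))
  tot <- Reduce(`+`, raw)
  support <- tot > eps
  norm <- lapply(raw, function(w) {
    out <- array(0, dim(w))
    out[support] <- w[support] / tot[support]
    out
  })
  structure(list(raw = raw, norm = norm, support = support,
                 bones = bones, eps = eps, config = config),
            class = "fusion_weights")
}

#' Polyaffine articulated-motion model
#'
#' Combines per-bone rotations into one smooth deformation.  Each bone
#' `t` rotates by its pitch `eta` (plus optional yaw/roll) about its own
#' local frame: the rotation acts about the transverse axis `e_z`
#' through the joint origin of the [bone_frame()].  The log-speed of
#' each rotation is divided by the fusion scale `S`, and one
#' sub-transformation displaces a point by the weight-blended average of
#' the per-bone exact exponential steps; composing
#' `k` sub-steps (weights re-evaluated along the way) yields the motion
#' at time `k/S`.
#'
#' @param frames List of [bone_frame()] objects (one per moving bone).
#' @param eta_deg Pitch angles (degrees), one per frame.
#' @param config A [fusion_config()].
#' @param weights A [fusion_weights()] over the same bones, or `NULL`
#'   for uniform weights (every bone weighted equally everywhere; with a
#'   single bone this is the exact rigid motion).
#' @param yaw_deg,roll_deg Optional rotations about the vertical and
#'   longitudinal axes (degrees, default 0).
#' @return An object of class `polyaffine_model`.
#' @export
polyaffine_model <- function(frames, eta_deg, config = fusion_config(),
                             weights = NULL, yaw_deg = 0, roll_deg = 0) {
  if (inherits(frames, "bone_frame")) frames <- list(frames)
  M <- length(frames)
  eta_deg <- rep_len(eta_deg, M)
  yaw_deg <- rep_len(yaw_deg, M)
  roll_deg <- rep_len(roll_deg, M)
  bones <- vector("list", M)
  for (t in seq_len(M)) {
    B <- frames[[t]]$axes
    R_loc <- rot_z(deg2rad(eta_deg[t])) %*% rot_y(deg2rad(roll_deg[t])) %*%
      rot_x(deg2rad(yaw_deg[t]))
    R <- B %*% R_loc %*% t(B)
    L <- log_rotation(R)
    aa <- axis_angle(R)
    alpha <- aa$alpha
    R_step <- if (alpha == 0) diag(3) else
      rotation_about_axis(aa$axis, alpha / config$S)
    bones[[t]] <- list(label = frames[[t]]$label,
                       origin = frames[[t]]$origin,
                       eta_deg = eta_deg[t], yaw_deg = yaw_deg[t],
                       roll_deg = roll_deg[t],
                       R = R, log_speed = L, alpha = alpha,
                       R_step = R_step)
  }
  structure(list(bones = bones, S = config$S, config = config,
                 weights = weights),
            class = "polyaffine_model")
}

#' @export
print.polyaffine_model <- function(x, ...) {
  cat(sprintf("<polyaffine_model> %d bone(s), S = %d, %s weights\n",
              length(x$bones), x$S,
              if (is.null(x$weights)) "uniform" else "Gaussian-map"))
  for (b in x$bones)
    cat(sprintf("  bone %s: pitch %.3g deg (alpha %.4g rad)\n",
                b$label, b$eta_deg, b$alpha))
  invisible(x)
}

#' Reverse a polyaffine model
#'
#' The inverse motion is obtained by negating every rotation angle; it
#' is exact for a single bone and approximate where weights blend.
#'
#' @param model A [polyaffine_model()].
#' @return A [polyaffine_model()] with opposite angles.
#' @export
invert_polyaffine <- function(model) {
  # rebuild directly from the transposed world rotations: conjugation by
  # the frame cancels, so reuse R rather than re-deriving local axes
  bones <- lapply(model$bones, function(b) {
    R <- t(b$R)
    L <- log_rotation(R)
    aa <- axis_angle(R)
    alpha <- aa$alpha
    R_step <- if (alpha == 0) diag(3) else
      rotation_about_axis(aa$axis, alpha / model$S)
    modifyList(b, list(eta_deg = -b$eta_deg, yaw_deg = -b$yaw_deg,
                       roll_deg = -b$roll_deg, R = R, log_speed = L,
                       alpha = alpha, R_step = R_step))
  })
  out <- model
  out$bones <- bones
  out
}

# raw weights of each bone at arbitrary points (n x M matrix)
eval_weights <- function(model, pts) {
  M <- length(model$bones)
  if (is.null(model$weights))
    return(matrix(1, nrow(pts), M))
  w <- vapply(model$weights$raw,
              function(map) tricubic_interpolate(map, pts),
              numeric(nrow(pts)))
  if (is.null(dim(w))) w <- matrix(w, nrow = nrow(pts))
  w[w < 0] <- 0                       # cubic overshoot guard
  w
}

#' One 1/S polyaffine sub-step
#'
#' Displaces points by the normalized weight blend of the per-bone exact
#' exponential steps (rotation by `alpha/S` about each bone origin).
#' Points in the identity region (total raw weight below the support
#' threshold) are returned unchanged.  Weights are looked up by
#' tricubic interpolation of the precomputed maps.
#'
#' @param pts Length-3 point or `n x 3` matrix (world units).
#' @param model A [polyaffine_model()].
#' @param w Optional precomputed `n x M` raw weight matrix (frozen
#'   weights); default evaluates the maps at `pts`.
#' @return Transformed points, same shape as `pts`.
#' @export
fusion_step <- function(pts, model, w = NULL) {
  was_vec <- is.null(dim(pts))
  if (was_vec) pts <- matrix(pts, ncol = 3)
  if (is.null(w)) w <- eval_weights(model, pts)
  tot <- rowSums(w)
  eps <- if (is.null(model$weights)) 0 else model$weights$eps
  act <- tot > eps
  out <- pts
  if (any(act)) {
    disp <- matrix(0, sum(act), 3)
    p <- pts[act, , drop = FALSE]
    for (t in seq_along(model$bones)) {
      b <- model$bones[[t]]
      moved <- sweep(sweep(p, 2, b$origin, "-") %*% t(b$R_step),
                     2, b$origin, "+")
      disp <- disp + (w[act, t] / tot[act]) * (moved - p)
    }
    out[act, ] <- p + disp
  }
  if (was_vec) out[1, ] else out
}

#' Compose polyaffine sub-steps on points
#'
#' Applies `k` compositions of the 1/S sub-transformation (`k = S`
#' yields the full motion).  By default the fusion weights are frozen
#' at each point's *initial* position (a material, Lagrangian reading
#' of the composition): a point deep inside one bone then moves exactly
#' rigidly for any rotation magnitude, and the blend across the joint
#' stays smooth.  With `freeze_weights = FALSE` the weights are
#' re-evaluated at every intermediate position (the Eulerian,
#' stationary-velocity reading); note that with truncated weight
#' support this strands material points whose trajectory sweeps outside
#' the reference support, so it is only meaningful for displacements
#' smaller than the kernel support radius.
#'
#' @param pts Length-3 point or `n x 3` matrix.
#' @param model A [polyaffine_model()].
#' @param k Number of sub-steps, `1 <= k <= S` (default `S`).
#' @param freeze_weights Evaluate weights only at the initial positions.
#' @param w Optional explicit `n x M` raw weight matrix (implies frozen
#'   weights).
#' @return Transformed points, same shape as `pts`.
#' @export
transform_points <- function(pts, model, k = model$S,
                             freeze_weights = TRUE, w = NULL) {
  stopifnot(k >= 1, k <= model$S)
  was_vec <- is.null(dim(pts))
  if (was_vec) pts <- matrix(pts, ncol = 3)
  if (is.null(w) && freeze_weights) w <- eval_weights(model, pts)
  for (i in seq_len(k)) pts <- fusion_step(pts, model, w)
  if (was_vec) pts[1, ] else pts
}

#' Warp a volume through a polyaffine model
#'
#' Inverse warping: every target voxel center is mapped back to its
#' source position by composing the reversed model (negated angles,
#' weights frozen at the target voxel) over all `S` sub-steps, and the
#' source volume is sampled there by tricubic interpolation (fill 0
#' outside the domain).
#'
#' @param vol A [volume()].
#' @param model A [polyaffine_model()] describing the *forward* motion.
#' @return A warped [volume()] on the same grid.
#' @export
warp_volume <- function(vol, model) {
  inv <- invert_polyaffine(model)
  d <- vol_dims(vol)
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                z = seq_len(d[3])))
  pts <- index_to_world(grid, d)
  src <- transform_points(pts, inv)
  volume(array(tricubic_interpolate(vol, src), d), vol$spacing)
}

#' Warp a label volume through a polyaffine model
#'
#' Same inverse mapping as [warp_volume()], with nearest-neighbor
#' lookup of the integer labels.
#'
#' @param labels A [label_volume()].
#' @param model A [polyaffine_model()].
#' @return A warped [label_volume()].
#' @export
warp_labels <- function(labels, model) {
  inv <- invert_polyaffine(model)
  d <- vol_dims(labels)
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                z = seq_len(d[3])))
  src <- transform_points(index_to_world(grid, d), inv)
  ind <- round(world_to_grid0(src, d)) + 1
  ok <- ind[, 1] >= 1 & ind[, 1] <= d[1] & ind[, 2] >= 1 &
    ind[, 2] <= d[2] & ind[, 3] >= 1 & ind[, 3] <= d[3]
  out <- integer(nrow(ind))
  out[ok] <- labels$data[ind[ok, , drop = FALSE]]
  label_volume(array(out, d))
}

#' Serialize / load a polyaffine model
#'
#' JSON layout: one record per bone (`label`, `eta_deg`, `origin`,
#' `axis` of the world rotation) plus `{S, sigma_f, k_f}`.  Weight maps
#' are not stored; rebuild them with [fusion_weights()] against the
#' label volume.
#'
#' @param model A [polyaffine_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_polyaffine <- function(model, path) {
  x <- list(S = model$S, sigma_f = model$config$sigma_f,
            k_f = model$config$k_f,
            bones = lapply(model$bones, function(b) {
              ax <- if (b$alpha < 1e-12) c(0, 0, 1) else
                c(b$log_speed[3, 2], b$log_speed[1, 3],
                  b$log_speed[2, 1]) / b$alpha
              list(label = b$label, eta_deg = b$eta_deg,
                   origin = b$origin, axis = ax)
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
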