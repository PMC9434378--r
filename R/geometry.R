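#' Cone-beam acquisition geometry
#'
#' Describes a calibrated cone-beam system: a point X-ray source, an
#' isocenter, and a flat detector whose center coincides with the
#' perpendicular projection of the source.  All distances are in voxel
#' units of the reference volume; detector pixels are converted to
#' *binned* pixels by the integer binning factor.
#'
#' @param sod Source-to-isocenter distance (voxel units), `> 0`.
#' @param sdd Source-to-detector distance (voxel units), `> sod`.
#' @param det_rows,det_cols Detector size in native (pre-binning) pixels.
#' @param det_pitch Detector pixel pitch (voxel units per native pixel).
#' @param binning Integer binning factor `b >= 1`; downstream images use
#'   binned pixels of size `det_pitch * b`.
#'
#' @return An object of class `cone_beam_geometry`.
#' @examples
#' g <- cone_beam_geometry(sod = 6550, sdd = 10000, det_rows = 768,
#'                         det_cols = 768, det_pitch = 1, binning = 6)
#' project_point(g, c(0, 0, 0))   # isocenter -> detector center
#' @export
cone_beam_geometry <- function(sod, sdd, det_rows, det_cols,
                               det_pitch = 1, binning = 1L) {
  stopifnot(is.numeric(sod), is.numeric(sdd), sod > 0, sdd > sod,
            det_pitch > 0, binning >= 1, binning == as.integer(binning),
            det_rows >= 1, det_cols >= 1)
  structure(list(sod = as.numeric(sod), sdd = as.numeric(sdd),
                 det_rows = as.integer(det_rows),
                 det_cols = as.integer(det_cols),
                 det_pitch = as.numeric(det_pitch),
                 binning = as.integer(binning)),
            class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf(
    "<cone_beam_geometry> SOD %.6g  SDD %.6g  (magnification %.4g)\n",
    x$sod, x$sdd, x$sdd / x$sod))
  cat(sprintf("  detector %d x %d px, pitch %.4g, binning %d -> image %d x %d\n",
              x$det_rows, x$det_cols, x$det_pitch, x$binning,
              x$det_rows %/% x$binning, x$det_cols %/% x$binning))
  invisible(x)
}

#' Magnification at the isocenter plane
#' @param geom A [cone_beam_geometry()].
#' @return `sdd / sod`.
#' @export
magnification <- function(geom) geom$sdd / geom$sod

#' Rigid + articulated pose parameter vector
#'
#' The registration vector holds 5 rigid parameters plus one pitch angle
#' per joint: translations `x_o, y_o, z_o` along the horizontal,
#' vertical, and projection axes (voxel units), rotations `theta_o`
#' (about the projection axis) and `phi_o` (the projection/gantry angle,
#' about the vertical axis) in degrees, and joint pitches `eta_joints`
#' (degrees) about each bone's transverse axis.  The rigid pitch
#' `eta_o` about the horizontal axis is not a free parameter: the parent
#' joint's pitch plays that role, so it is supplied separately where
#' needed to avoid redundancy.
#'
#' @param x_o,y_o,z_o Translations (voxel units).
#' @param theta_o,phi_o Rigid rotations (degrees).
#' @param eta_joints Numeric vector of N joint pitch angles (degrees);
#'   may be empty.
#' @return An object of class `pose_parameters`.
#' @export
pose_parameters <- function(x_o = 0, y_o = 0, z_o = 0,
                            theta_o = 0, phi_o = 0,
                            eta_joints = numeric()) {
  vals <- c(x_o, y_o, z_o, theta_o, phi_o, eta_joints)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  structure(list(x_o = as.numeric(x_o), y_o = as.numeric(y_o),
                 z_o = as.numeric(z_o), theta_o = as.numeric(theta_o),
                 phi_o = as.numeric(phi_o),
                 eta_joints = as.numeric(eta_joints)),
            class = "pose_parameters")
}

#' @export
print.pose_parameters <- function(x, ...) {
  cat(sprintf("<pose_parameters> t = (%.4g, %.4g, %.4g)  theta %.4g deg  phi %.4g deg\n",
              x$x_o, x$y_o, x$z_o, x$theta_o, x$phi_o))
  if (length(x$eta_joints))
    cat("  joint pitches (deg):", paste(signif(x$eta_joints, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten / rebuild a pose vector
#'
#' `pose_to_vector()` returns `c(x_o, y_o, z_o, theta_o, phi_o, eta_joints)`;
#' `vector_to_pose()` is its inverse given the number of joints.
#' @param pose A [pose_parameters()].
#' @return Numeric vector of length `5 + N`.
#' @export
pose_to_vector <- function(pose) {
  c(pose$x_o, pose$y_o, pose$z_o, pose$theta_o, pose$phi_o, pose$eta_joints)
}

#' @rdname pose_to_vector
#' @param v Numeric vector of length `5 + n_joints`.
#' @param n_joints Number of joint pitch entries at the tail of `v`.
#' @export
vector_to_pose <- function(v, n_joints = length(v) - 5L) {
  stopifnot(length(v) == 5L + n_joints)
  pose_parameters(v[1], v[2], v[3], v[4], v[5],
                  if (n_joints > 0) v[6:(5 + n_joints)] else numeric())
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Rigid rotation matrix of a pose
#'
#' Builds the object rotation `R = R_y(phi_o) %*% R_z(theta_o) %*% R_x(eta_o)`.
#' Axis convention: x is horizontal (parallel to detector rows), y vertical,
#' z the source-to-detector projection axis; `phi_o` rotates about y (the
#' projection angle), `theta_o` about z, and the pitch `eta_o` about x.
#'
#' @param pose A [pose_parameters()].
#' @param eta_o Rigid pitch about the horizontal axis (degrees); kept
#'   outside the pose vector (see [pose_parameters()]).
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(pose, eta_o = 0) {
  stopifnot(is.finite(eta_o))
  rot_y(deg2rad(pose$phi_o)) %*%
    rot_z(deg2rad(pose$theta_o)) %*%
    rot_x(deg2rad(eta_o))
}

#' Project a 3D point onto the binned detector
#'
#' Perspective projection with the source at `(0, 0, -sod)` and the
#' detector plane at `z = sdd - sod`, in world voxel units with the
#' isocenter at the origin.  Output coordinates are continuous binned
#' detector pixels with origin at the detector center:
#' `u = sdd * x / (sod + z) / (det_pitch * b)` and similarly for `v`.
#'
#' @param geom A [cone_beam_geometry()].
#' @param p A length-3 numeric vector, or an `n x 3` matrix of points.
#' @return A length-2 vector `(u, v)`, or an `n x 2` matrix.
#' @export
project_point <- function(geom, p) {
  was_vec <- is.null(dim(p))
  if (was_vec) p <- matrix(p, ncol = 3)
  stopifnot(ncol(p) == 3, all(is.finite(p)))
  denom <- geom$sod + p[, 3]
  if (any(denom <= 0))
    stop("point at or behind the X-ray source: projection diverges")
  s <- geom$sdd / denom / (geom$det_pitch * geom$binning)
  out <- cbind(u = p[, 1] * s, v = p[, 2] * s)
  if (was_vec) out[1, ] else out
}

#' Apply (or invert) the rigid part of a pose to 3D points
#'
#' `apply_rigid()` maps `p` to `R p + t`; `apply_rigid_inverse()` maps it
#' back with `R^T (p - t)`.
#'
#' @inheritParams rotation_matrix
#' @param p A length-3 vector or `n x 3` matrix of world points.
#' @return Transformed point(s), same shape as `p`.
#' @export
apply_rigid <- function(pose, p, eta_o = 0) {
  was_vec <- is.null(dim(p))
  if (was_vec) p <- matrix(p, ncol = 3)
  R <- rotation_matrix(pose, eta_o)
  t <- c(pose$x_o, pose$y_o, pose$z_o)
  out <- p %*% t(R)
  out <- sweep(out, 2, t, "+")
  if (was_vec) out[1, ] else out
}

#' @rdname apply_rigid
#' @export
apply_rigid_inverse <- function(pose, p, eta_o = 0) {
  was_vec <- is.null(dim(p))
  if (was_vec) p <- matrix(p, ncol = 3)
  R <- rotation_matrix(pose, eta_o)
  t <- c(pose$x_o, pose$y_o, pose$z_o)
  out <- sweep(p, 2, t, "-") %*% R
  if (was_vec) out[1, ] else out
}

#' Read / write a geometry config
#'
#' Geometry is serialized as a flat JSON or YAML block
#' `{sod, sdd, det_rows, det_cols, det_pitch, binning}`; the format is
#' chosen from the file extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_geometry()` returns a [cone_beam_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cone_beam_geometry(x$sod, x$sdd, x$det_rows, x$det_cols,
                     x$det_pitch, x$binning)
}

#' @rdname read_geometry
#' @param geom A [cone_beam_geometry()].
#' @export
write_geometry <- function(geom, path) {
  x <- unclass(geom)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}
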