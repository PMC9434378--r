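#' Configuration of the two-bone limb phantom
#'
#' The phantom emulates a dissected hindlimb: two elongated bones
#' ("femur" and "tibia") meeting at a joint, embedded in a soft-tissue
#' ellipsoid.  Each bone is a capsule with two spherical condyle-like
#' bulges at its joint end, so principal axes, frame signs and
#' scale-space keypoints are all well defined (a pure cylinder would
#' leave the longitudinal sign ambiguous).
#'
#' @param shape Grid size `c(nx, ny, nz)`; every axis `>= 4`.
#' @param femur_half_length,tibia_half_length Bone half-lengths (voxels).
#' @param femur_radius,tibia_radius Shaft radii (voxels).
#' @param joint_gap Gap between the two bones at the joint (voxels).
#' @param angle_deg Inter-bone angle between the two longitudinal axes
#'   (degrees).
#' @param mu_background,mu_soft,mu_bone Attenuation levels; must satisfy
#'   `mu_bone > mu_soft > mu_background >= 0`.
#' @param soft_padding Padding of the soft-tissue ellipsoid around the
#'   bones (voxels).
#' @param noise_sd Standard deviation of the texture noise added inside
#'   the object; clipped so the attenuation ordering is preserved.
#' @param seed Integer RNG seed; the phantom is bit-reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96L, 96L, 96L),
                           femur_half_length = 20, femur_radius = 5.5,
                           tibia_half_length = 17, tibia_radius = 4.5,
                           joint_gap = 7, angle_deg = 30,
                           mu_background = 0, mu_soft = 0.25, mu_bone = 1,
                           soft_padding = 8, noise_sd = 0.02,
                           seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 4),
            mu_bone > mu_soft, mu_soft > mu_background, mu_background >= 0,
            femur_half_length > 0, tibia_half_length > 0,
            femur_radius > 0, tibia_radius > 0, joint_gap >= 0,
            noise_sd >= 0)
  structure(list(shape = as.integer(shape),
                 femur_half_length = femur_half_length,
                 femur_radius = femur_radius,
                 tibia_half_length = tibia_half_length,
                 tibia_radius = tibia_radius,
                 joint_gap = joint_gap, angle_deg = angle_deg,
                 mu_background = mu_background, mu_soft = mu_soft,
                 mu_bone = mu_bone, soft_padding = soft_padding,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# squared distance from every grid point to segment P--Q
grid_dist2_segment <- function(X, Y, Z, P, Q) {
  v <- Q - P
  vv <- sum(v^2)
  if (vv == 0) {
    return((X - P[1])^2 + (Y - P[2])^2 + (Z - P[3])^2)
  }
  t <- ((X - P[1]) * v[1] + (Y - P[2]) * v[2] + (Z - P[3]) * v[3]) / vv
  t[t < 0] <- 0; t[t > 1] <- 1
  (X - (P[1] + t * v[1]))^2 + (Y - (P[2] + t * v[2]))^2 +
    (Z - (P[3] + t * v[3]))^2
}

grid_dist2_point <- function(X, Y, Z, P)
  (X - P[1])^2 + (Y - P[2])^2 + (Z - P[3])^2

#' Generate the two-bone limb phantom
#'
#' Builds a deterministic synthetic limb volume from a
#' [phantom_config()]: two capsule bones with condyle bulges meeting at
#' joint `j2` (the knee), inside a soft-tissue ellipsoid, with seeded,
#' ordering-preserving texture noise.  The returned labels are the exact
#' generative bone masks (label 1 = femur, label 2 = tibia); joint
#' origins are in world coordinates (`j1` = hip end of the femur, the
#' parent joint; `j2` = the inter-bone junction).
#'
#' @param config A [phantom_config()].
#' @return A list with elements `volume` ([volume()]), `labels`
#'   ([label_volume()]), `joints` (list `j1`, `j2` of world points),
#'   `axes` (list of unit longitudinal directions `femur`, `tibia`,
#'   pointing away from the junction), and `config`.
#' @export
make_limb_phantom <- function(config = phantom_config()) {
  d <- config$shape
  half_ang <- deg2rad(config$angle_deg) / 2
  a1 <- c(sin(half_ang), cos(half_ang), 0)    # femur axis, points up
  a2 <- c(sin(half_ang), -cos(half_ang), 0)   # tibia axis, points down
  J <- c(0, 0, 0)                              # junction at volume center
  g2 <- config$joint_gap / 2

  cx <- seq_len(d[1]) - 1 - (d[1] - 1) / 2
  cy <- seq_len(d[2]) - 1 - (d[2] - 1) / 2
  cz <- seq_len(d[3]) - 1 - (d[3] - 1) / 2
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  bone_mask <- function(axis, half_length, radius) {
    P <- J + (g2 + radius) * axis
    Q <- J + (g2 + 2 * half_length - radius) * axis
    m <- grid_dist2_segment(X, Y, Z, P, Q) <= radius^2
    rb <- 1.3 * radius
    bc <- J + (g2 + rb) * axis
    for (s in c(-1, 1)) {
      centre <- bc + s * 0.8 * radius * c(0, 0, 1)
      m <- m | (grid_dist2_point(X, Y, Z, centre) <= rb^2)
    }
    list(mask = m, far_end = J + (g2 + 2 * half_length) * axis)
  }
  femur <- bone_mask(a1, config$femur_half_length, config$femur_radius)
  tibia <- bone_mask(a2, config$tibia_half_length, config$tibia_radius)
  if (any(femur$mask & tibia$mask))
    stop("phantom config error: bones overlap; increase joint_gap or angle")
  if (any(femur$mask[c(1, d[1]), , ]) || any(femur$mask[, c(1, d[2]), ]) ||
      any(femur$mask[, , c(1, d[3])]) || any(tibia$mask[c(1, d[1]), , ]) ||
      any(tibia$mask[, c(1, d[2]), ]) || any(tibia$mask[, , c(1, d[3])]))
    stop("phantom config error: bones do not fit inside the volume")

  bones <- femur$mask | tibia$mask
  ext <- apply(which(bones, arr.ind = TRUE), 2, range)
  centre_idx <- colMeans(ext)
  semi <- pmin((ext[2, ] - ext[1, ]) / 2 + config$soft_padding,
               (d - 1) / 2 - 1)
  soft <- (((X - (centre_idx[1] - 1 - (d[1] - 1) / 2)) / semi[1])^2 +
           ((Y - (centre_idx[2] - 1 - (d[2] - 1) / 2)) / semi[2])^2 +
           ((Z - (centre_idx[3] - 1 - (d[3] - 1) / 2)) / semi[3])^2) <= 1

  vol <- array(config$mu_background, d)
  vol[soft] <- config$mu_soft
  vol[bones] <- config$mu_bone

  if (config$noise_sd > 0) {
    gap <- min(config$mu_soft - config$mu_background,
               config$mu_bone - config$mu_soft)
    clip <- 0.45 * gap
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(config$seed)
    inside <- soft | bones
    noise <- stats::rnorm(sum(inside), 0, config$noise_sd)
    vol[inside] <- vol[inside] + pmin(pmax(noise, -clip), clip)
  }

  lab <- array(0L, d)
  lab[femur$mask] <- 1L
  lab[tibia$mask] <- 2L
  list(volume = volume(vol),
       labels = label_volume(lab),
       joints = list(j1 = femur$far_end, j2 = J),
       axes = list(femur = a1, tibia = a2),
       config = config)
}
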