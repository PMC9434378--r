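# trilinear sampling of a 3D array at world points (fill 0 outside)
trilinear_interpolate <- function(vol, p) {
  v <- if (inherits(vol, "volume")) vol$data else vol
  d <- dim(v)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  q <- world_to_grid0(p, d)
  i0 <- floor(q)
  tt <- q - i0
  out <- numeric(nrow(p))
  for (dz in 0:1) {
    kz <- i0[, 3] + dz
    wz <- if (dz == 0) 1 - tt[, 3] else tt[, 3]
    okz <- kz >= 0 & kz < d[3]
    for (dy in 0:1) {
      ky <- i0[, 2] + dy
      wyz <- (if (dy == 0) 1 - tt[, 2] else tt[, 2]) * wz
      oky <- okz & ky >= 0 & ky < d[2]
      for (dx in 0:1) {
        kx <- i0[, 1] + dx
        ok <- oky & kx >= 0 & kx < d[1]
        if (!any(ok)) next
        w <- (if (dx == 0) 1 - tt[ok, 1] else tt[ok, 1]) * wyz[ok]
        flat <- kx[ok] + d[1] * (ky[ok] + d[2] * kz[ok]) + 1
        out[ok] <- out[ok] + w * v[flat]
      }
    }
  }
  out
}

# binned detector pixel-center coordinates and ray bookkeeping
detector_rays <- function(geom) {
  nu <- geom$det_cols %/% geom$binning
  nv <- geom$det_rows %/% geom$binning
  u <- seq_len(nu) - 1 - (nu - 1) / 2
  v <- seq_len(nv) - 1 - (nv - 1) / 2
  px <- geom$det_pitch * geom$binning
  pts <- cbind(rep(u, each = nv) * px, rep(v, times = nu) * px,
               geom$sdd - geom$sod)
  list(nu = nu, nv = nv, u = u, v = v, det_pts = pts)
}

# shared ray-marching loop: `sample_fun(pts)` returns per-point values
raymarch <- function(vol_dims_, geom, pose, eta_o, step, sample_fun) {
  rays <- detector_rays(geom)
  src <- c(0, 0, -geom$sod)
  dirs <- sweep(rays$det_pts, 2, src, "-")
  len <- sqrt(rowSums(dirs^2))
  dirs <- dirs / len
  t_obj <- c(pose$x_o, pose$y_o, pose$z_o)  # posed volume center
  radius <- sqrt(sum(((vol_dims_ - 1) / 2)^2)) + 1
  s_c <- (t_obj[1] - src[1]) * dirs[, 1] + (t_obj[2] - src[2]) * dirs[, 2] +
    (t_obj[3] - src[3]) * dirs[, 3]
  n_steps <- ceiling(2 * radius / step)
  acc <- numeric(nrow(dirs))
  offs <- (seq_len(n_steps) - (n_steps + 1) / 2) * step
  for (o in offs) {
    s <- s_c + o
    pts <- cbind(src[1] + s * dirs[, 1], src[2] + s * dirs[, 2],
                 src[3] + s * dirs[, 3])
    acc <- acc + sample_fun(pts)
  }
  matrix(acc * step, nrow = rays$nv, ncol = rays$nu)
}

#' Simulate a radiograph by ray-driven projection
#'
#' For every binned detector pixel, integrates the trilinearly sampled
#' attenuation along the source-to-pixel-center ray (step 0.5 voxel by
#' default, scaled by the step length).  The rigid pose places the
#' volume in the acquisition frame; sampling happens in the volume
#' frame via the inverse pose.  Image rows run along the vertical
#' detector axis (v), columns along the horizontal axis (u).
#'
#' @param vol A [volume()].
#' @param geom A [cone_beam_geometry()].
#' @param pose A [pose_parameters()] (rigid part only is used).
#' @param eta_o Rigid pitch about the horizontal axis (degrees).
#' @param step Ray sampling step (voxels).
#' @return An object of class `radiograph`: `image` (matrix, binned
#'   pixels), `geom`, `pose`, `eta_o`, `I0` (`NA` until noise is
#'   applied).
#' @export
project_volume <- function(vol, geom, pose = pose_parameters(),
                           eta_o = 0, step = 0.5) {
  img <- raymarch(vol_dims(vol), geom, pose, eta_o, step, function(pts)
    trilinear_interpolate(vol, apply_rigid_inverse(pose, pts, eta_o)))
  structure(list(image = img, geom = geom, pose = pose, eta_o = eta_o,
                 I0 = NA_real_), class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d binned px, range [%.4g, %.4g]%s\n",
              nrow(x$image), ncol(x$image), min(x$image), max(x$image),
              if (is.finite(x$I0)) sprintf(", Poisson I0 = %.4g", x$I0) else ""))
  invisible(x)
}

#' Project a bone mask
#'
#' A binned pixel is set iff any bone material lies along its ray
#' (line integral of the binary bone mask strictly positive).
#'
#' @param labels A [label_volume()].
#' @param bone Label id (or vector of labels: union mask).
#' @inheritParams project_volume
#' @return Logical matrix of the binned image size.
#' @export
project_mask <- function(labels, bone, geom, pose = pose_parameters(),
                         eta_o = 0, step = 0.5) {
  mask <- array(as.numeric(labels$data %in% bone), vol_dims(labels))
  img <- raymarch(vol_dims(labels), geom, pose, eta_o, step, function(pts)
    trilinear_interpolate(mask, apply_rigid_inverse(pose, pts, eta_o)))
  img > 1e-9
}

#' Apply Poisson counting noise to a radiograph
#'
#' The noiseless image is scaled so its maximum equals `I0`, and every
#' pixel is replaced by a Poisson draw with the scaled pixel value as
#' mean.  Deterministic given `seed`.
#'
#' @param rad A `radiograph` (or plain nonnegative matrix).
#' @param I0 Maximum intensity (expected counts at the brightest pixel).
#' @param seed Integer RNG seed.
#' @return Same type as the input, with noisy values (and `I0` recorded
#'   on a `radiograph`).
#' @export
add_poisson_noise <- function(rad, I0, seed = 1L) {
  img <- if (inherits(rad, "radiograph")) rad$image else rad
  stopifnot(all(img >= 0), I0 > 0)
  mx <- max(img)
  if (mx <= 0) stop("all-zero image: cannot scale to I0")
  scaled <- img * (I0 / mx)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  noisy <- matrix(stats::rpois(length(scaled), scaled), nrow(scaled))
  if (inherits(rad, "radiograph")) {
    rad$image <- noisy
    rad$I0 <- I0
    rad
  } else noisy
}
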