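#' 3D scalar volume
#'
#' A light container around a numeric 3D array of attenuation values.
#' Voxel indices are 1-based in R; the *world* frame places the origin at
#' the grid center, so world coordinates of voxel `(i, j, k)` are
#' `(i, j, k) - 1 - (dim - 1) / 2`.  This world frame is the one used by
#' the acquisition geometry (isocenter at the volume center).
#'
#' @param data A numeric 3D array with all dimensions `>= 4` (tricubic
#'   interpolation support) and finite values.
#' @param spacing Physical voxel size (micrometres); metadata only, all
#'   computations are in voxel units.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            all(dim(data) >= 4), all(is.finite(data)))
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %.4g, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing, min(x$data), max(x$data)))
  invisible(x)
}

#' Integer label volume
#'
#' Same grid as a [volume()], with `0` background and `1..B` bone labels
#' (6-connected components, sorted by descending size).
#'
#' @param data Integer 3D array of labels.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data) {
  stopifnot(is.array(data), length(dim(data)) == 3, all(data >= 0))
  storage.mode(data) <- "integer"
  structure(list(data = data), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tb <- table(x$data[x$data > 0])
  cat(sprintf("<label_volume> %s, %d labels (sizes: %s)\n",
              paste(dim(x$data), collapse = " x "), length(tb),
              paste(as.integer(tb), collapse = ", ")))
  invisible(x)
}

vol_dims <- function(x) dim(if (inherits(x, "volume") ||
                                inherits(x, "label_volume")) x$data else x)

# world <-> continuous 0-based grid coordinate conversions
world_to_grid0 <- function(p, dims) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  sweep(p, 2, (dims - 1) / 2, "+")
}
index_to_world <- function(ind, dims) {
  if (is.null(dim(ind))) ind <- matrix(ind, ncol = 3)
  sweep(ind - 1, 2, (dims - 1) / 2, "-")
}

#' Otsu threshold of a volume
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning
#' `[min, max]` of the data; ties are broken toward the lower threshold.
#' The returned scalar is the bin edge separating the two classes;
#' binarize with `values > threshold`.
#'
#' @param vol A [volume()] or numeric array.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(vol, n_bins = 256L) {
  v <- if (inherits(vol, "volume")) vol$data else vol
  rng <- range(v)
  if (diff(rng) <= 0)
    stop("degenerate histogram: volume is constant, Otsu threshold undefined")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L),
                     n_bins), nbins = n_bins)
  n <- sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(h)[-n_bins]
  w1 <- n - w0
  s0 <- cumsum(h * mids)[-n_bins]
  mu_tot <- sum(h * mids)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_tot * w0[valid] - n * s0[valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  k <- which.max(bcv)          # first max = lower threshold on ties
  edges[k + 1L]
}

# shift a 3D logical/numeric array by s along axis, padding with `fill`
shift3 <- function(a, s, axis, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- vector("list", 3)
  idx_dst <- vector("list", 3)
  for (ax in 1:3) idx_src[[ax]] <- idx_dst[[ax]] <- seq_len(d[ax])
  if (s > 0) {
    idx_dst[[axis]] <- (s + 1):d[axis]
    idx_src[[axis]] <- 1:(d[axis] - s)
  } else if (s < 0) {
    idx_dst[[axis]] <- 1:(d[axis] + s)
    idx_src[[axis]] <- (1 - s):d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# separable binary dilation/erosion with a cubic structuring element
binary_dilate <- function(mask, size) {
  r <- (size - 1L) %/% 2L
  if (r == 0L) return(mask)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (s in c(-r:-1, 1:r)) acc <- acc | shift3(out, s, axis, FALSE)
    out <- acc
  }
  out
}
binary_erode <- function(mask, size) !binary_dilate(!mask, size)

#' 6-connected component labeling
#'
#' Labels the `TRUE` voxels of a binary mask by face (6-) connectivity.
#' Component membership is computed on the voxel adjacency graph; labels
#' are renumbered by descending component size (ties by smallest voxel
#' index).
#'
#' @param mask Logical 3D array.
#' @return Integer array, `0` background, `1..B` components.
#' @export
label_components6 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  rank <- integer(prod(d))
  rank[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  offs <- c(1L, d[1], d[1] * d[2])
  edges <- NULL
  for (ax in 1:3) {
    sel <- ai[, ax] < d[ax]
    nb <- idx[sel] + offs[ax]
    sel2 <- mask[nb]
    if (any(sel2))
      edges <- rbind(edges, cbind(rank[idx[sel][sel2]], rank[nb[sel2]]))
  }
  memb <- if (is.null(edges)) seq_along(idx) else {
    g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
    igraph::components(g)$membership
  }
  sizes <- tabulate(memb)
  ord <- order(-sizes, vapply(seq_along(sizes),
                              function(c) min(idx[memb == c]), 0))
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(sizes)
  lab[idx] <- relab[memb]
  lab
}

#' Segment bones in a volume
#'
#' Pipeline: Otsu binarization (removes soft tissue), removal of
#' 6-connected components smaller than `min_voxels`, morphological
#' closing with a cubic `close_size^3` structuring element (fills
#' internal cavities), and a final 6-connected labeling with labels
#' sorted by descending size.
#'
#' @param vol A [volume()].
#' @param min_voxels Components with fewer voxels are discarded.
#' @param close_size Odd edge length of the cubic closing element.
#' @return A [label_volume()].
#' @export
segment_bones <- function(vol, min_voxels = 50L, close_size = 5L) {
  stopifnot(close_size >= 1, close_size %% 2 == 1)
  thr <- otsu_threshold(vol)
  mask <- vol$data > thr
  if (!any(mask)) stop("empty segmentation: no voxels above Otsu threshold")
  lab <- label_components6(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) stop("empty segmentation: all components below min_voxels")
  mask <- array(lab %in% keep, dim(lab))
  mask <- binary_erode(binary_dilate(mask, close_size), close_size)
  label_volume(label_components6(mask))
}

#' Principal-axis frame of a bone segment
#'
#' PCA of the (unweighted) voxel coordinates of one label defines the
#' bone local frame: the longitudinal axis `e_y` is the largest-variance
#' eigenvector, the vertical axis `e_x` the middle one, and the
#' transverse axis `e_z` completes a right-handed triple.  The joint
#' origin is placed by sliding the center of mass along the longitudinal
#' axis by the semi-axis length `L = 2 * sqrt(sigma_max)`; `end_hint`
#' (+1 / -1) selects which end, replacing a visual check.
#'
#' @param labels A [label_volume()].
#' @param bone Label id.
#' @param end_hint `+1` or `-1`: direction of the origin slide along `e_y`.
#' @return An object of class `bone_frame` with fields `origin`, `axes`
#'   (3x3, columns `e_x`, `e_y`, `e_z`), `eigenvalues`
#'   (`sigma_max >= sigma_mid >= sigma_min`, coordinate variances),
#'   `com`, and `label`.
#' @export
bone_frame <- function(labels, bone, end_hint = 1) {
  stopifnot(end_hint %in% c(-1, 1))
  idx <- which(labels$data == bone)
  if (length(idx) < 4L) stop("bone label empty or too small for a frame")
  d <- vol_dims(labels)
  pts <- index_to_world(arrayInd(idx, d), d)
  C <- stats::cov(pts)
  eg <- eigen(C, symmetric = TRUE)
  vals <- eg$values                      # descending
  if (vals[3] <= 0 || (vals[1] - vals[2]) / vals[1] < 0.01)
    stop("ambiguous frame: voxel cloud is (near-)isotropic, sigma_max ~ sigma_mid")
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  e_y <- fix_sign(eg$vectors[, 1])
  e_x <- fix_sign(eg$vectors[, 2])
  e_z <- c(e_x[2] * e_y[3] - e_x[3] * e_y[2],
           e_x[3] * e_y[1] - e_x[1] * e_y[3],
           e_x[1] * e_y[2] - e_x[2] * e_y[1])
  com <- colMeans(pts)
  L <- 2 * sqrt(vals[1])
  structure(list(origin = com + end_hint * L * e_y,
                 axes = cbind(e_x = e_x, e_y = e_y, e_z = e_z),
                 eigenvalues = vals, com = com, label = bone),
            class = "bone_frame")
}

#' @export
print.bone_frame <- function(x, ...) {
  cat(sprintf("<bone_frame> label %d  origin (%.3g, %.3g, %.3g)\n",
              x$label, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  eigenvalues %.4g >= %.4g >= %.4g, longitudinal axis (%.3f, %.3f, %.3f)\n",
              x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3],
              x$axes[1, 2], x$axes[2, 2], x$axes[3, 2]))
  invisible(x)
}

# Lagrange cubic weights for nodes {-1, 0, 1, 2} at fraction t in [0, 1)
cubic_weights <- function(t) {
  cbind(-t * (t - 1) * (t - 2) / 6,
        (t + 1) * (t - 1) * (t - 2) / 2,
        -(t + 1) * t * (t - 2) / 2,
        (t + 1) * t * (t - 1) / 6)
}

#' Tricubic interpolation
#'
#' Local separable Lagrange interpolation on the 4x4x4 integer-voxel
#' neighborhood of each query point: along each axis a 3rd-order
#' polynomial is fit to the four surrounding samples.  On-lattice points
#' reproduce the stored voxel values exactly; per-axis cubic polynomials
#' are reproduced exactly in the interior.  Neighborhood samples falling
#' outside the grid contribute the fill value 0.
#'
#' @param vol A [volume()] or numeric 3D array.
#' @param p Length-3 world point or `n x 3` matrix of world points.
#' @return Numeric vector of interpolated values.
#' @export
tricubic_interpolate <- function(vol, p) {
  v <- if (inherits(vol, "volume")) vol$data else vol
  d <- dim(v)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  q <- world_to_grid0(p, d)              # continuous 0-based grid coords
  i0 <- floor(q)
  tt <- q - i0
  wx <- cubic_weights(tt[, 1]); wy <- cubic_weights(tt[, 2])
  wz <- cubic_weights(tt[, 3])
  base <- i0                             # 0-based index of node offset 0
  out <- numeric(nrow(p))
  for (dz in 0:3) {
    kz <- base[, 3] + dz - 1             # 0-based grid index
    okz <- kz >= 0 & kz < d[3]
    for (dy in 0:3) {
      ky <- base[, 2] + dy - 1
      oky <- okz & ky >= 0 & ky < d[2]
      wyz <- wy[, dy + 1] * wz[, dz + 1]
      for (dx in 0:3) {
        kx <- base[, 1] + dx - 1
        ok <- oky & kx >= 0 & kx < d[1]
        if (!any(ok)) next
        flat <- kx[ok] + d[1] * (ky[ok] + d[2] * kz[ok]) + 1
        out[ok] <- out[ok] + wx[ok, dx + 1] * wyz[ok] * v[flat]
      }
    }
  }
  out
}
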