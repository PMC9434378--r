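#' Convert between detector and image-pixel coordinates
#'
#' Detector coordinates `(u, v)` are continuous binned pixels with the
#' origin at the detector center (the convention of
#' [project_point()]); image-pixel coordinates `(row, col)` are 1-based
#' matrix indices with `row` along v and `col` along u.
#'
#' @param uv Length-2 vector or `n x 2` matrix of `(u, v)`.
#' @param dims Image dimensions `c(rows, cols)`.
#' @return The converted coordinates, same shape.
#' @export
detector_to_pixel <- function(uv, dims) {
  was_vec <- is.null(dim(uv))
  if (was_vec) uv <- matrix(uv, ncol = 2)
  out <- cbind(row = uv[, 2] + 1 + (dims[1] - 1) / 2,
               col = uv[, 1] + 1 + (dims[2] - 1) / 2)
  if (was_vec) out[1, ] else out
}

#' @rdname detector_to_pixel
#' @param rc Length-2 vector or `n x 2` matrix of `(row, col)`.
#' @export
pixel_to_detector <- function(rc, dims) {
  was_vec <- is.null(dim(rc))
  if (was_vec) rc <- matrix(rc, ncol = 2)
  out <- cbind(u = rc[, 2] - 1 - (dims[2] - 1) / 2,
               v = rc[, 1] - 1 - (dims[1] - 1) / 2)
  if (was_vec) out[1, ] else out
}

#' Encode a landmark as a voting vector field
#'
#' At every mask pixel, stores the unit vector pointing from the pixel
#' center toward the landmark; the field is zero outside the mask and
#' at the landmark pixel itself.
#'
#' @param mask Logical matrix (the bone segment).
#' @param landmark Length-2 `(row, col)` continuous pixel coordinate.
#' @return Array `dim(mask) x 2`, channels `(d_row, d_col)`.
#' @export
encode_vector_field <- function(mask, landmark) {
  stopifnot(is.matrix(mask), any(mask), all(is.finite(landmark)))
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  dr <- landmark[1] - idx[, 1]
  dc <- landmark[2] - idx[, 2]
  nrm <- sqrt(dr^2 + dc^2)
  nz <- nrm > 0
  field <- array(0, c(d, 2))
  if (any(nz)) {
    field[cbind(idx[nz, , drop = FALSE], 1L)] <- dr[nz] / nrm[nz]
    field[cbind(idx[nz, , drop = FALSE], 2L)] <- dc[nz] / nrm[nz]
  }
  field
}

#' Voting configuration
#'
#' @param n_hypotheses Number of pixel-pair ray intersections sampled
#'   per landmark.
#' @param inlier_cos Cosine threshold above which a mask pixel's vector
#'   counts as an inlier for a hypothesis.
#' @param eps Regularizer in the inverse-covariance weight
#'   `omega = 1 / (sigma + eps)`.
#' @param refine_radius Consensus radius (pixels): the final estimate
#'   averages only hypotheses within this distance of the best-scoring
#'   one, which keeps gross outlier hypotheses from biasing the mean.
#' @param seed Integer RNG seed for the pair sampling.
#' @return An object of class `voting_config`.
#' @export
voting_config <- function(n_hypotheses = 128L, inlier_cos = 0.99,
                          eps = 1e-6, refine_radius = 3, seed = 1L) {
  stopifnot(n_hypotheses >= 1, inlier_cos > 0, inlier_cos <= 1, eps > 0,
            refine_radius > 0)
  structure(list(n_hypotheses = as.integer(n_hypotheses),
                 inlier_cos = inlier_cos, eps = eps,
                 refine_radius = refine_radius,
                 seed = as.integer(seed)), class = "voting_config")
}

#' Vote a landmark position from a vector field
#'
#' RANSAC-style voting: pixel pairs are sampled from the mask, each
#' pair's two rays are intersected to form a hypothesis, and every
#' hypothesis is scored by the number of mask pixels whose stored
#' vector points at it within the angular inlier threshold.  The
#' landmark observation is the score-weighted mean of the hypotheses
#' `mu_hat`, the scalar covariance `sigma` (score-weighted mean squared
#' distance of the hypotheses to `mu_hat`), and the inverse-covariance
#' weight `omega = 1 / (sigma + eps)` used by the registration cost.
#'
#' @param field Array `(rows, cols, 2)` of (predicted or encoded)
#'   voting vectors.
#' @param mask Logical matrix restricting which pixels vote.
#' @param config A [voting_config()].
#' @return An object of class `landmark_observation2d`: `mu_hat`
#'   (`(row, col)`), `sigma`, `omega`, `n_valid` hypotheses.
#' @export
vote_landmark <- function(field, mask, config = voting_config()) {
  idx <- which(mask, arr.ind = TRUE)
  vr <- field[cbind(idx, 1L)]
  vc <- field[cbind(idx, 2L)]
  nrm <- sqrt(vr^2 + vc^2)
  usable <- nrm > 0.5
  if (sum(usable) < 2)
    stop("degenerate voting: fewer than 2 usable mask pixels")
  p <- idx[usable, , drop = FALSE]
  vr <- vr[usable] / nrm[usable]
  vc <- vc[usable] / nrm[usable]
  n <- nrow(p)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  i1 <- sample.int(n, config$n_hypotheses, replace = TRUE)
  i2 <- sample.int(n, config$n_hypotheses, replace = TRUE)
  ok <- i1 != i2
  cross <- vr[i1] * vc[i2] - vc[i1] * vr[i2]
  ok <- ok & abs(cross) > 1e-9
  dr <- p[i2, 1] - p[i1, 1]
  dc <- p[i2, 2] - p[i1, 2]
  t1 <- (dr * vc[i2] - dc * vr[i2]) / cross
  t2 <- (dr * vc[i1] - dc * vr[i1]) / cross
  ok <- ok & t1 >= 0 & t2 >= 0
  if (!any(ok))
    stop("degenerate voting: all sampled vector pairs are parallel")
  hr <- p[i1[ok], 1] + t1[ok] * vr[i1[ok]]
  hc <- p[i1[ok], 2] + t1[ok] * vc[i1[ok]]

  # score every hypothesis by angular-consistency inliers
  m <- length(hr)
  score <- numeric(m)
  for (j in seq_len(m)) {
    gr <- hr[j] - p[, 1]
    gc <- hc[j] - p[, 2]
    gn <- sqrt(gr^2 + gc^2)
    pos <- gn > 0
    cosang <- (gr[pos] * vr[pos] + gc[pos] * vc[pos]) / gn[pos]
    score[j] <- sum(cosang >= config$inlier_cos) + sum(!pos)
  }
  best <- which.max(score)
  keep <- (hr - hr[best])^2 + (hc - hc[best])^2 <= config$refine_radius^2
  w <- if (sum(score[keep]) > 0) score[keep] / sum(score[keep]) else
    rep(1 / sum(keep), sum(keep))
  mu <- c(sum(w * hr[keep]), sum(w * hc[keep]))
  sigma <- sum(w * ((hr[keep] - mu[1])^2 + (hc[keep] - mu[2])^2))
  structure(list(mu_hat = c(row = mu[1], col = mu[2]), sigma = sigma,
                 omega = 1 / (sigma + config$eps), n_valid = m),
            class = "landmark_observation2d")
}

#' @export
print.landmark_observation2d <- function(x, ...) {
  cat(sprintf("<landmark_observation2d> mu = (%.3f, %.3f)  sigma %.4g  omega %.4g  (%d hypotheses)\n",
              x$mu_hat[1], x$mu_hat[2], x$sigma, x$omega, x$n_valid))
  invisible(x)
}
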