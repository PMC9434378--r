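#' Landmark selection configuration
#'
#' Controls the shortest-coordinate-variance greedy selection: `k` is
#' the number of landmarks requested, `lambda` the scale threshold
#' multiplying the distance floor, and `use_sqrt` decides whether the
#' floor is `lambda * sqrt(sigma_min)` (default: eigenvalues are
#' variances, distances are lengths) or `lambda * sigma_min`.
#'
#' @param k Number of landmarks, `>= 1`.
#' @param lambda Scale threshold `> 0` (unitless); chosen heuristically
#'   per bone shape and size (values around 2--4 are typical).
#' @param use_sqrt Compare pairwise distances against
#'   `lambda * sqrt(sigma_min)` (`TRUE`, default) or
#'   `lambda * sigma_min`.
#' @param tie_break Deterministic ordering rule for candidates at equal
#'   distance from the center of mass; `"lexicographic"` (lowest
#'   coordinate first) is the only built-in rule.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(k = 20L, lambda = 2.5, use_sqrt = TRUE,
                             tie_break = "lexicographic") {
  stopifnot(k >= 1, lambda > 0, tie_break == "lexicographic")
  structure(list(k = as.integer(k), lambda = lambda, use_sqrt = use_sqrt,
                 tie_break = tie_break), class = "selection_config")
}

#' Candidate points: bone voxels
#'
#' All voxel centers of one bone label in world coordinates, ordered by
#' increasing flat (column-major) voxel index.  With
#' `surface_only = TRUE`, only voxels with at least one 6-neighbor
#' outside the label are returned, restricting candidates to the bone
#' surface.
#'
#' @param labels A [label_volume()].
#' @param bone Label id.
#' @param surface_only Keep only surface voxels.
#' @return `n x 3` matrix of world coordinates.
#' @export
candidate_bone_voxels <- function(labels, bone, surface_only = FALSE) {
  mask <- labels$data == bone
  if (!any(mask)) stop("empty bone label: no candidate voxels")
  if (surface_only) {
    interior <- binary_erode(mask, 3L)
    mask <- mask & !interior
  }
  d <- vol_dims(labels)
  index_to_world(arrayInd(which(mask), d), d)
}

# separable 3D Gaussian smoothing, truncated kernel of given half width
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

smooth3 <- function(a, sigma, radius = ceiling(3 * sigma)) {
  k <- gauss_kernel(sigma, radius)
  r <- (length(k) - 1L) / 2L
  out <- a
  for (axis in 1:3) {
    acc <- out * k[r + 1L]
    for (s in seq_len(r)) {
      acc <- acc + k[r + 1L + s] * shift3(out, -s, axis, 0) +
        k[r + 1L - s] * shift3(out, s, axis, 0)
    }
    out <- acc
  }
  out
}

# running max over a 3-wide window along the given axes (pad -Inf)
local_max3 <- function(a, axes = 1:3) {
  out <- a
  for (axis in axes)
    out <- pmax(out, shift3(out, 1L, axis, -Inf),
                shift3(out, -1L, axis, -Inf))
  out
}
local_min3 <- function(a, axes = 1:3) -local_max3(-a, axes)

#' 3D difference-of-Gaussians keypoints of a bone
#'
#' Simplified volumetric scale-space keypoints: the volume is smoothed
#' at each scale, adjacent scales are subtracted, and local extrema over
#' the 3x3x3x3 space-scale neighborhood are kept if they lie within 2
#' voxels of the bone label and their |DoG| response exceeds a contrast
#' floor.  Only positions are produced (no orientation histograms or
#' descriptors): the downstream selection scheme needs positions only.
#'
#' @param vol A [volume()].
#' @param labels A [label_volume()].
#' @param bone Label id.
#' @param scales Increasing Gaussian sigmas (voxels), at least 2.
#' @param contrast Contrast floor as a fraction of the maximum |DoG|
#'   response.
#' @return `n x 3` matrix of world coordinates, ordered by decreasing
#'   |DoG| response; zero rows when no extremum qualifies.
#' @export
dog_keypoints3d <- function(vol, labels, bone,
                            scales = c(1.6, 2.26, 3.2, 4.53),
                            contrast = 0.05) {
  stopifnot(length(scales) >= 2, all(diff(scales) > 0))
  d <- vol_dims(vol)
  sm <- lapply(scales, function(s) smooth3(vol$data, s))
  dogs <- lapply(seq_len(length(scales) - 1L),
                 function(i) sm[[i + 1L]] - sm[[i]])
  near <- binary_dilate(labels$data == bone, 5L)   # within 2 voxels
  floor_val <- contrast * max(abs(unlist(lapply(dogs, range))))
  pts <- NULL; resp <- NULL
  for (i in seq_along(dogs)) {
    cur <- dogs[[i]]
    up <- if (i < length(dogs)) dogs[[i + 1L]] else
      array(-Inf, d)
    dn <- if (i > 1) dogs[[i - 1L]] else array(-Inf, d)
    is_max <- cur >= local_max3(cur) & cur >= local_max3(up) &
      cur >= local_max3(dn)
    up2 <- if (i < length(dogs)) dogs[[i + 1L]] else array(Inf, d)
    dn2 <- if (i > 1) dogs[[i - 1L]] else array(Inf, d)
    is_min <- cur <= local_min3(cur) & cur <= local_min3(up2) &
      cur <= local_min3(dn2)
    keep <- (is_max | is_min) & abs(cur) >= floor_val & near
    if (any(keep)) {
      idx <- which(keep)
      pts <- rbind(pts, index_to_world(arrayInd(idx, d), d))
      resp <- c(resp, abs(cur[idx]))
    }
  }
  if (is.null(pts)) return(matrix(numeric(), ncol = 3))
  pts[order(-resp), , drop = FALSE]
}

#' Greedy shortest-coordinate-variance landmark selection
#'
#' Selects up to `config$k` landmarks from a candidate set: the first is
#' the candidate farthest from the bone center of mass; each subsequent
#' one is the farthest-from-CoM candidate whose distance to *every*
#' already selected landmark is at least the floor
#' `lambda * sqrt(sigma_min)` (or `lambda * sigma_min`, see
#' [selection_config()]), with `sigma_min` the bone's smallest PCA
#' coordinate variance.  Stops when `k` landmarks are found or the
#' candidates are exhausted.
#'
#' @param candidates `n x 3` matrix of world points (e.g. from
#'   [candidate_bone_voxels()] or [dog_keypoints3d()]).
#' @param frame A [bone_frame()] providing `sigma_min` and the CoM.
#' @param config A [selection_config()].
#' @param type Tag stored with the set (`"bounding"` or `"sift"`).
#' @return An object of class `landmark_set3d`: fields `coords`
#'   (`m x 3`), `bone`, `type`, `sigma_min`, `s_min` (the distance
#'   floor actually used, divided by lambda), `lambda`, `com`, and
#'   `exhausted` (`TRUE` when fewer than `k` landmarks satisfied the
#'   floor).
#' @export
select_landmarks <- function(candidates, frame, config = selection_config(),
                             type = "bounding") {
  stopifnot(is.matrix(candidates), ncol(candidates) == 3,
            nrow(candidates) >= 1)
  com <- frame$com
  sigma_min <- frame$eigenvalues[3]
  s_min <- if (config$use_sqrt) sqrt(sigma_min) else sigma_min
  floor_d2 <- (config$lambda * s_min)^2

  d2com <- (candidates[, 1] - com[1])^2 + (candidates[, 2] - com[2])^2 +
    (candidates[, 3] - com[3])^2
  ord <- order(-d2com, candidates[, 1], candidates[, 2], candidates[, 3])
  cand <- candidates[ord, , drop = FALSE]

  sel <- matrix(numeric(), ncol = 3)
  alive <- rep(TRUE, nrow(cand))
  while (nrow(sel) < config$k && any(alive)) {
    i <- which(alive)[1]                  # farthest-from-CoM survivor
    p <- cand[i, ]
    sel <- rbind(sel, p)
    alive[i] <- FALSE
    d2 <- (cand[, 1] - p[1])^2 + (cand[, 2] - p[2])^2 +
      (cand[, 3] - p[3])^2
    alive <- alive & d2 >= floor_d2
  }
  rownames(sel) <- NULL
  structure(list(coords = sel, bone = frame$label, type = type,
                 sigma_min = sigma_min, s_min = s_min,
                 lambda = config$lambda, com = com,
                 exhausted = nrow(sel) < config$k),
            class = "landmark_set3d")
}

#' @export
print.landmark_set3d <- function(x, ...) {
  cat(sprintf("<landmark_set3d> bone %s, type %s: %d landmarks (lambda %.3g, floor %.3g)%s\n",
              x$bone, x$type, nrow(x$coords), x$lambda,
              x$lambda * x$s_min,
              if (x$exhausted) " [candidates exhausted]" else ""))
  invisible(x)
}

#' Write / read 3D landmark sets
#'
#' Landmarks are stored as CSV (`bone,type,index,x,y,z`, world voxel
#' units) with a JSON sidecar per set carrying `lambda`, `sigma_min`
#' and the CoM.
#'
#' @param sets A list of `landmark_set3d` objects.
#' @param path CSV output path; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_landmarks3d <- function(sets, path) {
  if (inherits(sets, "landmark_set3d")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(s) {
    data.frame(bone = s$bone, type = s$type,
               index = seq_len(nrow(s$coords)),
               x = s$coords[, 1], y = s$coords[, 2], z = s$coords[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  meta <- lapply(sets, function(s)
    list(bone = s$bone, type = s$type, lambda = s$lambda,
         sigma_min = s$sigma_min, com = s$com, exhausted = s$exhausted))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_landmarks3d
#' @export
read_landmarks3d <- function(path) {
  rows <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  lapply(meta, function(m) {
    sel <- rows$bone == m$bone & rows$type == m$type
    structure(list(
      coords = unname(as.matrix(rows[sel, c("x", "y", "z")])),
      bone = m$bone, type = m$type, sigma_min = m$sigma_min,
      s_min = sqrt(m$sigma_min), lambda = m$lambda,
      com = as.numeric(unlist(m$com)), exhausted = isTRUE(m$exhausted)),
      class = "landmark_set3d")
  })
}
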