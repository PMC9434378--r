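#' Acquisition plan for simulated radiograph datasets
#'
#' Enumerates a full simulation campaign: a grid of joint articulations
#' (one angle list per joint; every combination becomes one deformed
#' volume), a set of projection-angle intervals (centers with a common
#' half-width), a number of projections per interval, and jitter ranges
#' for the remaining acquisition parameters.  The manifest size is
#' `prod(lengths(articulation_grids)) * length(interval_centers) *
#' n_projections`.
#'
#' @param articulation_grids List of numeric vectors: per-joint pitch
#'   angles (degrees).
#' @param interval_centers Projection-angle interval centers (degrees).
#' @param interval_half_width Half-width of each interval (degrees);
#'   the projection angle `phi` is drawn uniformly inside.
#' @param n_projections Projections drawn per (volume, interval).
#' @param sod,sdd `c(mean, half_range)` source distances (voxels).
#' @param xyz_range `c(x, y, z)` half-ranges of the translations
#'   (voxels), drawn uniformly in `+/- range`.
#' @param theta_range,eta_range Half-ranges (degrees) of the rotations
#'   about the two horizontal axes (`theta_o` about the projection
#'   axis, `eta_o` about the horizontal axis).
#' @param I0 `c(mean, half_range)` Poisson scaling intensity.
#' @param split_fractions Named fractions `train`, `val`, `test`
#'   (must sum to 1).
#' @param seed Integer seed controlling jitter and the split shuffle.
#' @return An object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(articulation_grids,
                             interval_centers,
                             interval_half_width = 1.5,
                             n_projections = 13L,
                             sod = c(6550, 180), sdd = c(10000, 540),
                             xyz_range = c(180, 120, 180),
                             theta_range = 15, eta_range = 15,
                             I0 = c(2000, 350),
                             split_fractions = c(train = 0.75, val = 0.20,
                                                 test = 0.05),
                             seed = 1L) {
  stopifnot(is.list(articulation_grids), length(articulation_grids) >= 1,
            n_projections >= 1, length(sod) == 2, length(sdd) == 2,
            length(xyz_range) == 3, abs(sum(split_fractions) - 1) < 1e-9,
            all(is.finite(unlist(articulation_grids))),
            all(is.finite(interval_centers)))
  structure(list(articulation_grids = articulation_grids,
                 interval_centers = interval_centers,
                 interval_half_width = interval_half_width,
                 n_projections = as.integer(n_projections),
                 sod = sod, sdd = sdd, xyz_range = xyz_range,
                 theta_range = theta_range, eta_range = eta_range,
                 I0 = I0, split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  nv <- prod(lengths(x$articulation_grids))
  cat(sprintf("<acquisition_plan> %d articulated volumes x %d intervals x %d projections = %d entries\n",
              nv, length(x$interval_centers), x$n_projections,
              nv * length(x$interval_centers) * x$n_projections))
  invisible(x)
}

#' Reference simulation campaigns
#'
#' `training_plan()` is the dataset the detection network is trained
#' on: a 6 x 5 articulation grid (femur pitches equally spaced over
#' -30..35 degrees, tibia over -20..35), forty +/-1.5-degree projection
#' intervals equally sampled from -30..30 and 150..210 degrees, and 13
#' projections per interval (15,600 radiographs in total), with
#' SOD 6550+/-180, SDD 10000+/-540, translations +/-180/120/180 voxels,
#' horizontal-axis rotations +/-15 degrees and Poisson I0 2000+/-350.
#' `study_plan()` is the independent evaluation campaign: a 3 x 3
#' articulation grid (femur -19..30, tibia -16..30 degrees), eight
#' +/-7.5-degree intervals over the same two ranges, SOD 6450+/-180 and
#' SDD 10200+/-540.
#'
#' @param n_projections Projections per interval (13 for training; for
#'   the study campaign choose so that the wanted sample count results).
#' @param seed Integer seed.
#' @return An [acquisition_plan()].
#' @export
training_plan <- function(n_projections = 13L, seed = 1L) {
  acquisition_plan(
    articulation_grids = list(femur = seq(-30, 35, length.out = 6),
                              tibia = seq(-20, 35, length.out = 5)),
    interval_centers = c(seq(-30, 30, length.out = 20),
                         seq(150, 210, length.out = 20)),
    interval_half_width = 1.5, n_projections = n_projections,
    sod = c(6550, 180), sdd = c(10000, 540), seed = seed)
}

#' @rdname training_plan
#' @export
study_plan <- function(n_projections = 13L, seed = 1L) {
  acquisition_plan(
    articulation_grids = list(femur = seq(-19, 30, length.out = 3),
                              tibia = seq(-16, 30, length.out = 3)),
    interval_centers = c(seq(-30, 30, length.out = 4),
                         seq(150, 210, length.out = 4)),
    interval_half_width = 7.5, n_projections = n_projections,
    sod = c(6450, 180), sdd = c(10200, 540), seed = seed)
}

#' Enumerate an acquisition plan into a manifest
#'
#' Expands every (articulated volume, angle interval, projection index)
#' triple and draws the jittered acquisition parameters from the seeded
#' ranges; assigns train/val/test splits by a seeded shuffle honouring
#' the configured fractions.
#'
#' @param plan An [acquisition_plan()].
#' @return A data.frame with one row per radiograph: `vol_id`, one
#'   `eta_<joint>` column per joint, `interval`, `proj`, the drawn
#'   `phi`, `theta`, `eta_o`, `x`, `y`, `z`, `sod`, `sdd`, `I0`,
#'   `noise_seed`, and `split`.
#' @export
build_manifest <- function(plan) {
  grids <- plan$articulation_grids
  art <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(art) <- paste0("eta_", if (is.null(names(grids)))
    seq_along(grids) else names(grids))
  n_vol <- nrow(art)
  n_int <- length(plan$interval_centers)
  n_pr <- plan$n_projections
  n <- n_vol * n_int * n_pr

  idx <- expand.grid(proj = seq_len(n_pr), interval = seq_len(n_int),
                     vol_id = seq_len(n_vol))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(plan$seed)
  runif2 <- function(half) stats::runif(n, -half, half)
  m <- data.frame(
    vol_id = idx$vol_id,
    art[idx$vol_id, , drop = FALSE],
    interval = idx$interval, proj = idx$proj,
    phi = plan$interval_centers[idx$interval] +
      runif2(plan$interval_half_width),
    theta = runif2(plan$theta_range),
    eta_o = runif2(plan$eta_range),
    x = runif2(plan$xyz_range[1]),
    y = runif2(plan$xyz_range[2]),
    z = runif2(plan$xyz_range[3]),
    sod = plan$sod[1] + runif2(plan$sod[2]),
    sdd = plan$sdd[1] + runif2(plan$sdd[2]),
    I0 = plan$I0[1] + runif2(plan$I0[2]),
    noise_seed = sample.int(.Machine$integer.max %/% 2L, n),
    row.names = NULL)
  counts <- floor(plan$split_fractions * n)
  counts[1] <- n - sum(counts[-1])
  tags <- rep(names(plan$split_fractions), counts)
  m$split <- tags[sample.int(n)]
  m
}

#' Generate dataset samples from a manifest
#'
#' For each manifest row: builds the polyaffine model for the row's
#' articulation, co-transforms the 3D reference landmarks, warps the
#' volume and labels (cached per articulated volume), projects the
#' radiograph, per-bone masks and ground-truth 2D landmarks with the
#' row's jittered geometry and rigid pose, and applies Poisson noise.
#' With `render = FALSE` only the ground-truth 2D landmarks and poses
#' are produced (no ray marching), which is enough for registration
#' experiments.
#'
#' @param manifest Rows from [build_manifest()].
#' @param vol A [volume()] (reference model).
#' @param labels A [label_volume()] of the bones.
#' @param frames List of [bone_frame()] (ordered as the plan's joints).
#' @param landmark_sets List of `landmark_set3d` reference sets.
#' @param fusion A [fusion_config()].
#' @param det `c(det_rows, det_cols)` native detector size.
#' @param det_pitch,binning Detector pitch and binning factor.
#' @param render `"none"` (landmark ground truth only), `"masks"`
#'   (adds projected per-bone masks), or `"full"` (adds the noisy
#'   radiograph); logical `TRUE`/`FALSE` map to `"full"`/`"none"`.
#' @param weights Optional precomputed [fusion_weights()].
#' @return List of samples; each has `pose`, `eta_o`, `geom`, `split`,
#'   `landmarks2d` (list per set: `m x 2` matrices of binned pixels),
#'   `landmarks3d_posed`, and if rendered `radiograph` and `masks`.
#' @export
generate_dataset <- function(manifest, vol, labels, frames, landmark_sets,
                             fusion = fusion_config(),
                             det = c(768L, 768L), det_pitch = 1,
                             binning = 6L, render = "full",
                             weights = NULL) {
  if (is.logical(render)) render <- if (render) "full" else "none"
  render <- match.arg(render, c("none", "masks", "full"))
  if (is.null(weights))
    weights <- fusion_weights(labels, vapply(frames, `[[`, 0, "label"),
                              fusion)
  cache <- new.env(parent = emptyenv())
  eta_cols <- grep("^eta_", names(manifest), value = TRUE)
  eta_cols <- setdiff(eta_cols, "eta_o")
  samples <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    key <- paste0("v", row$vol_id)
    if (is.null(cache[[key]])) {
      etas <- as.numeric(row[eta_cols])
      model <- polyaffine_model(frames, etas, fusion, weights)
      lm3 <- lapply(landmark_sets, function(s)
        transform_points(s$coords, model))
      entry <- list(model = model, lm3 = lm3)
      if (render != "none") {
        if (render == "full") entry$wvol <- warp_volume(vol, model)
        entry$wlab <- warp_labels(labels, model)
      }
      cache[[key]] <- entry
    }
    entry <- cache[[key]]
    geom <- cone_beam_geometry(row$sod, row$sdd, det[1], det[2],
                               det_pitch, binning)
    pose <- pose_parameters(row$x, row$y, row$z, row$theta, row$phi,
                            eta_joints = as.numeric(row[eta_cols]))
    lm2 <- lapply(entry$lm3, function(p)
      project_point(geom, apply_rigid(pose, p, row$eta_o)))
    smp <- list(pose = pose, eta_o = row$eta_o, geom = geom,
                split = row$split, landmarks2d = lm2,
                landmarks3d_posed = entry$lm3, vol_id = row$vol_id,
                I0 = row$I0)
    if (render != "none") {
      smp$masks <- lapply(vapply(frames, `[[`, 0, "label"), function(b)
        project_mask(entry$wlab, b, geom, pose, row$eta_o))
      if (render == "full") {
        rad <- project_volume(entry$wvol, geom, pose, row$eta_o)
        smp$radiograph <- add_poisson_noise(rad, row$I0, row$noise_seed)
      }
    }
    samples[[r]] <- smp
  }
  samples
}

#' Read / write an acquisition plan as YAML
#' @param path File path.
#' @return `read_plan()` returns an [acquisition_plan()].
#' @export
read_plan <- function(path) {
  x <- yaml::read_yaml(path)
  acquisition_plan(lapply(x$articulation_grids, as.numeric),
                   as.numeric(x$interval_centers),
                   x$interval_half_width, x$n_projections,
                   as.numeric(x$sod), as.numeric(x$sdd),
                   as.numeric(x$xyz_range), x$theta_range, x$eta_range,
                   as.numeric(x$I0),
                   unlist(x$split_fractions), x$seed)
}

#' @rdname read_plan
#' @param plan An [acquisition_plan()].
#' @export
write_plan <- function(plan, path) {
  yaml::write_yaml(unclass(plan), path)
  invisible(path)
}
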