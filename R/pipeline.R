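#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations and a single global seed from which
#' all stage seeds are derived deterministically.  The fusion defaults
#' here are scaled to the phantom geometry (bone radii of a few voxels),
#' not to a full-resolution CT.
#'
#' @param phantom A [phantom_config()].
#' @param selection A [selection_config()].
#' @param fusion A [fusion_config()].
#' @param voting A [voting_config()].
#' @param registration A [registration_config()].
#' @param landmark_type `"bounding"` or `"sift"`: which reference sets
#'   drive registration.
#' @param det `c(det_rows, det_cols)` native detector pixels.
#' @param det_pitch,binning Detector pitch (voxel units) and binning.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            selection = selection_config(k = 20L,
                                                         lambda = 1.4),
                            fusion = fusion_config(S = 18L, sigma_f = 3,
                                                   k_f = 9L),
                            voting = voting_config(),
                            registration = registration_config(),
                            landmark_type = "bounding",
                            det = c(576L, 576L), det_pitch = 1,
                            binning = 6L, seed = 1L) {
  structure(list(phantom = phantom, selection = selection,
                 fusion = fusion, voting = voting,
                 registration = registration,
                 landmark_type = match.arg(landmark_type,
                                           c("bounding", "sift")),
                 det = as.integer(det), det_pitch = det_pitch,
                 binning = as.integer(binning), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build the reference model from the phantom
#'
#' Runs the reference-side chain once: phantom generation,
#' segmentation ([segment_bones()]), bone frames (with the origin end
#' chosen against the phantom's known joint positions, standing in for
#' the visual check), 3D landmark extraction (bounding and
#' scale-space sets per bone), and fusion weight maps.
#'
#' @param config A [pipeline_config()].
#' @return A list: `phantom`, `seg` (label volume), `frames`,
#'   `landmarks` (named list `bounding`/`sift`, each a per-bone list),
#'   `weights`.
#' @export
build_reference <- function(config = pipeline_config()) {
  ph <- make_limb_phantom(config$phantom)
  seg <- segment_bones(ph$volume)
  joints <- list(ph$joints$j1, ph$joints$j2)
  frames <- lapply(1:2, function(b) {
    f_plus <- bone_frame(seg, b, end_hint = 1)
    f_minus <- bone_frame(seg, b, end_hint = -1)
    if (sum((f_plus$origin - joints[[b]])^2) <=
        sum((f_minus$origin - joints[[b]])^2)) f_plus else f_minus
  })
  bounding <- lapply(1:2, function(b)
    select_landmarks(candidate_bone_voxels(seg, b, surface_only = TRUE),
                     frames[[b]], config$selection, type = "bounding"))
  sift <- lapply(1:2, function(b) {
    kp <- dog_keypoints3d(ph$volume, seg, b)
    if (nrow(kp) == 0) kp <- candidate_bone_voxels(seg, b, TRUE)
    select_landmarks(kp, frames[[b]], config$selection, type = "sift")
  })
  weights <- fusion_weights(seg, 1:2, config$fusion)
  list(phantom = ph, seg = seg, frames = frames,
       landmarks = list(bounding = bounding, sift = sift),
       weights = weights)
}

# draw one random pose + geometry from the simulated acquisition ranges
draw_acquisition <- function(det, det_pitch, binning,
                             sod = c(6550, 180), sdd = c(10000, 540),
                             xyz = c(180, 120, 180), theta = 15,
                             eta_o = 15,
                             eta_grid = list(c(-30, 35), c(-20, 35)),
                             phi_ranges = list(c(-30, 30), c(150, 210))) {
  rng <- phi_ranges[[sample.int(length(phi_ranges), 1)]]
  geom <- cone_beam_geometry(sod[1] + stats::runif(1, -sod[2], sod[2]),
                             sdd[1] + stats::runif(1, -sdd[2], sdd[2]),
                             det[1], det[2], det_pitch, binning)
  tau <- pose_parameters(
    x_o = stats::runif(1, -xyz[1], xyz[1]),
    y_o = stats::runif(1, -xyz[2], xyz[2]),
    z_o = stats::runif(1, -xyz[3], xyz[3]),
    theta_o = stats::runif(1, -theta, theta),
    phi_o = stats::runif(1, rng[1], rng[2]),
    eta_joints = vapply(eta_grid, function(r) stats::runif(1, r[1], r[2]),
                        0))
  list(geom = geom, tau = tau,
       eta_o = stats::runif(1, -eta_o, eta_o))
}

#' Pose-recovery experiment
#'
#' Monte-Carlo study of the registration stage alone: poses and
#' acquisition geometries are drawn from the simulated training
#' ranges, landmark observations are produced by the articulated
#' forward model itself (optionally perturbed by Gaussian pixel noise
#' of the typical detection error level), and the staged solver
#' reconstructs every pose from a zero initialization.
#'
#' @param reference Output of [build_reference()].
#' @param config A [pipeline_config()].
#' @param n_trials Number of random poses.
#' @param noise_px Gaussian noise sd added to each observed coordinate
#'   (binned pixels); 0 for noiseless observations.
#' @param seed Integer seed.
#' @return A list: `summary` (from [evaluate_errors()]), `errors`
#'   (matrix of per-trial absolute errors), `estimates`, `truths`.
#' @export
pose_recovery_experiment <- function(reference,
                                     config = pipeline_config(),
                                     n_trials = 50L, noise_px = 0,
                                     seed = 1L) {
  sets <- reference$landmarks[[config$landmark_type]]
  fm <- forward_model(sets, reference$frames, config$fusion,
                      reference$weights)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  estimates <- truths <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    acq <- draw_acquisition(config$det, config$det_pitch, config$binning)
    uv <- forward_landmarks(acq$tau, fm, acq$geom, acq$eta_o)
    if (noise_px > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_px), nrow(uv))
    obs <- observation_set(uv, omega = 1, eta_o = acq$eta_o)
    est <- register_pose(obs, fm, acq$geom, config$registration)
    estimates[[i]] <- est
    truths[[i]] <- acq$tau
  }
  summary <- evaluate_errors(estimates, truths)
  list(summary = summary, errors = attr(summary, "errors"),
       estimates = estimates, truths = truths)
}

#' Run the pipeline end to end
#'
#' Chains phantom generation, segmentation, frame and landmark
#' extraction, dataset simulation, landmark observation and staged
#' registration, and error evaluation.  Operating modes:
#' `"oracle"` uses the dataset's ground-truth 2D landmarks directly
#' (exercises geometry, articulation and registration with no imaging);
#' `"voting"` renders per-bone masks, encodes the ground-truth voting
#' vector fields, and runs the full RANSAC voting before registration
#' (exercises every stage except the network); `"network"` additionally
#' trains a small detection network on rendered radiographs and infers
#' the fields (desk-scale only).
#'
#' @param config A [pipeline_config()].
#' @param mode `"oracle"`, `"voting"`, or `"network"`.
#' @param n_samples Number of registered samples.
#' @param noise_px Gaussian noise added to oracle observations
#'   (pixels); ignored by the other modes.
#' @param out_dir Optional directory for `report.json` and
#'   `errors.csv`.
#' @return A list: `summary`, `errors`, `estimates`, `truths`,
#'   `reference`, `config`, `mode`.
#' @export
run_end_to_end <- function(config = pipeline_config(),
                           mode = c("oracle", "voting", "network"),
                           n_samples = 20L, noise_px = 0,
                           out_dir = NULL) {
  mode <- match.arg(mode)
  reference <- build_reference(config)
  sets <- reference$landmarks[[config$landmark_type]]
  fm <- forward_model(sets, reference$frames, config$fusion,
                      reference$weights)

  # the rendered field of view at phantom scale needs modest offsets
  plan <- acquisition_plan(
    articulation_grids = list(j1 = c(-20, 0, 25), j2 = c(-15, 0, 20)),
    interval_centers = c(-20, 0, 20, 160, 180, 200),
    interval_half_width = 5, n_projections = 4L,
    sod = c(6550, 180), sdd = c(10000, 540),
    xyz_range = if (mode == "oracle") c(180, 120, 180) else c(40, 30, 40),
    theta_range = 15, eta_range = 15,
    seed = config$seed + 1L)
  manifest <- build_manifest(plan)
  n_samples <- min(n_samples, nrow(manifest))
  manifest <- manifest[seq_len(n_samples), , drop = FALSE]

  samples <- generate_dataset(
    manifest, reference$phantom$volume, reference$seg, reference$frames,
    sets, config$fusion, det = config$det, det_pitch = config$det_pitch,
    binning = config$binning,
    render = switch(mode, oracle = "none", voting = "masks",
                    network = "full"),
    weights = reference$weights)

  img_dims <- c(config$det[1] %/% config$binning,
                config$det[2] %/% config$binning)
  nets <- NULL
  if (mode == "network") {
    k <- config$selection$k
    nets <- vector("list", 2)
    for (b in 1:2) {
      train_ss <- lapply(samples, function(s) {
        rc <- detector_to_pixel(s$landmarks2d[[b]], img_dims)
        make_training_sample(s$radiograph$image, s$masks[[b]], rc)
      })
      net <- build_bonenet(bonenet_config(input_size = img_dims[1], k = k),
                           seed = config$seed + 10L + b)
      nets[[b]] <- train_bonenet(train_ss, net,
                                 train_config(seed = config$seed + 20L + b))
    }
  }

  estimates <- truths <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    s <- samples[[i]]
    if (mode == "oracle") {
      uv <- do.call(rbind, s$landmarks2d)
      if (noise_px > 0)
        uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_px), nrow(uv))
      obs <- observation_set(uv, omega = 1, eta_o = s$eta_o)
    } else {
      uvs <- list(); oms <- list()
      for (b in 1:2) {
        rc_gt <- detector_to_pixel(s$landmarks2d[[b]], img_dims)
        k <- nrow(rc_gt)
        uv_b <- matrix(NA_real_, k, 2); om_b <- numeric(k)
        voters <- if (mode == "voting") {
          lapply(seq_len(k), function(j) tryCatch(
            vote_landmark(encode_vector_field(s$masks[[b]], rc_gt[j, ]),
                          s$masks[[b]],
                          modifyList(config$voting,
                                     list(seed = config$voting$seed + i))),
            error = function(e) NULL))
        } else {
          detect_landmarks(nets[[b]]$net, s$radiograph$image,
                           mask = s$masks[[b]], config = config$voting)
        }
        for (j in seq_len(k)) {
          v <- voters[[j]]
          if (!is.null(v)) {
            uv_b[j, ] <- pixel_to_detector(v$mu_hat, img_dims)
            om_b[j] <- v$omega
          }
        }
        uvs[[b]] <- uv_b; oms[[b]] <- om_b
      }
      obs <- observation_set(do.call(rbind, uvs), unlist(oms),
                             eta_o = s$eta_o)
    }
    estimates[[i]] <- register_pose(obs, fm, s$geom, config$registration)
    truths[[i]] <- s$pose
  }
  summary <- evaluate_errors(estimates, truths)
  out <- list(summary = summary, errors = attr(summary, "errors"),
              estimates = estimates, truths = truths,
              reference = reference, config = config, mode = mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(attr(summary, "errors")),
                     file.path(out_dir, "errors.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(mode = mode, n_samples = n_samples,
           summary = summary,
           converged = vapply(estimates, function(e) e$converged, TRUE)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
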