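#' Articulated forward model for registration
#'
#' Precomputes everything needed to map the pose vector to 2D landmark
#' projections: the 3D reference landmarks of each joint's bone, the
#' bone frames, and (for the polyaffine articulation mode) the fusion
#' weights *frozen at the reference landmark positions* -- matching how
#' ground-truth landmark coordinates are generated, while keeping the
#' residual smooth in the joint angles.  The `rigid` mode instead moves
#' each bone as a kinematic chain: the parent pitch rotates every bone
#' about the parent joint origin, the child pitch only the child bone
#' about its own origin.
#'
#' @param landmark_sets List of `landmark_set3d`, one per joint, ordered
#'   parent first (joint i's set lies on joint i's bone).
#' @param frames List of [bone_frame()] in the same order.
#' @param fusion A [fusion_config()].
#' @param weights A [fusion_weights()] over the same bones (required
#'   for `mode = "polyaffine"` unless uniform weights are intended).
#' @param mode `"polyaffine"` (default) or `"rigid"`.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(landmark_sets, frames, fusion = fusion_config(),
                          weights = NULL, mode = "polyaffine") {
  stopifnot(length(landmark_sets) == length(frames),
            mode %in% c("polyaffine", "rigid"))
  ref <- do.call(rbind, lapply(landmark_sets, function(s) s$coords))
  set_id <- rep(seq_along(landmark_sets),
                vapply(landmark_sets, function(s) nrow(s$coords), 0L))
  w_ref <- w_norm <- active <- NULL
  if (mode == "polyaffine") {
    probe <- polyaffine_model(frames, rep(0, length(frames)), fusion,
                              weights)
    w_ref <- eval_weights(probe, ref)
    tot <- rowSums(w_ref)
    eps <- if (is.null(weights)) 0 else weights$eps
    active <- tot > eps
    w_norm <- w_ref
    w_norm[active, ] <- w_ref[active, , drop = FALSE] / tot[active]
    w_norm[!active, ] <- 0
  }
  structure(list(ref = ref, set_id = set_id, frames = frames,
                 fusion = fusion, weights = weights, w_ref = w_ref,
                 w_norm = w_norm, active = active,
                 mode = mode, n_joints = length(frames)),
            class = "forward_model")
}

# articulated 3D positions of the reference landmarks for joint pitches
articulate_landmarks <- function(fm, eta_joints) {
  if (all(abs(eta_joints) < 1e-15)) return(fm$ref)
  if (fm$mode == "polyaffine") {
    model <- polyaffine_model(fm$frames, eta_joints, fm$fusion, fm$weights)
    # frozen normalized weights make each 1/S sub-step a fixed affine
    # map per landmark: x <- M x + b, iterated S times (identical to
    # composing fusion_step with the frozen weight matrix, but without
    # per-step weight arithmetic)
    n <- nrow(fm$ref)
    M <- matrix(0, n, 9)
    b <- matrix(0, n, 3)
    for (t in seq_along(model$bones)) {
      bt <- model$bones[[t]]
      M <- M + fm$w_norm[, t] * rep(as.numeric(bt$R_step), each = n)
      ob <- bt$origin - as.numeric(bt$R_step %*% bt$origin)
      b <- b + fm$w_norm[, t] * rep(ob, each = n)
    }
    x <- fm$ref
    for (s in seq_len(model$S)) {
      x <- cbind(M[, 1] * x[, 1] + M[, 4] * x[, 2] + M[, 7] * x[, 3] +
                   b[, 1],
                 M[, 2] * x[, 1] + M[, 5] * x[, 2] + M[, 8] * x[, 3] +
                   b[, 2],
                 M[, 3] * x[, 1] + M[, 6] * x[, 2] + M[, 9] * x[, 3] +
                   b[, 3])
    }
    x[!fm$active, ] <- fm$ref[!fm$active, ]
    x
  } else {
    out <- fm$ref
    # children first, then the parent sweeps everything
    for (i in rev(seq_len(fm$n_joints))) {
      fr <- fm$frames[[i]]
      R <- rotation_about_axis(fr$axes[, 3], deg2rad(eta_joints[i]))
      move <- if (i == 1L) rep(TRUE, nrow(out)) else fm$set_id >= i
      out[move, ] <- sweep(sweep(out[move, , drop = FALSE], 2, fr$origin,
                                 "-") %*% t(R), 2, fr$origin, "+")
    }
    out
  }
}

#' Project reference landmarks under a pose
#'
#' Applies the articulation (joint pitches), the rigid pose, and the
#' cone-beam projection to every reference landmark of the forward
#' model.  Landmarks falling at or behind the source are flagged and
#' excluded.
#'
#' @param tau A [pose_parameters()] with `length(eta_joints)` equal to
#'   the forward model's joint count.
#' @param fm A [forward_model()].
#' @param geom A [cone_beam_geometry()].
#' @param eta_o Fixed rigid pitch (degrees).
#' @return `n x 2` matrix of `(u, v)` binned detector coordinates, with
#'   attribute `valid` (logical; `FALSE` rows are `NA` and were behind
#'   the source).
#' @export
forward_landmarks <- function(tau, fm, geom, eta_o = 0) {
  p3 <- articulate_landmarks(fm, tau$eta_joints)
  p3 <- apply_rigid(tau, p3, eta_o)
  valid <- geom$sod + p3[, 3] > 0
  out <- matrix(NA_real_, nrow(p3), 2)
  if (any(!valid))
    warning(sprintf("%d landmark(s) at/behind the source excluded",
                    sum(!valid)))
  if (any(valid))
    out[valid, ] <- project_point(geom, p3[valid, , drop = FALSE])
  attr(out, "valid") <- valid
  out
}

#' Observation set for registration
#'
#' @param uv `n x 2` matrix of measured landmark coordinates
#'   (binned detector pixels, detector-center origin).
#' @param omega Positive weights (inverse hypothesis covariances); a
#'   scalar is recycled.
#' @param sod,sdd,eta_o Fixed (known) acquisition quantities.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(uv, omega = 1, sod = NULL, sdd = NULL,
                            eta_o = 0) {
  stopifnot(is.matrix(uv), ncol(uv) == 2)
  omega <- rep_len(omega, nrow(uv))
  stopifnot(all(omega >= 0))
  structure(list(uv = uv, omega = omega, sod = sod, sdd = sdd,
                 eta_o = eta_o), class = "observation_set")
}

#' Weighted reprojection cost
#'
#' The exact weighted sum of squared pixel residuals between measured
#' and computed landmark projections.
#'
#' @param tau A [pose_parameters()].
#' @param obs An [observation_set()].
#' @param fm A [forward_model()].
#' @param geom A [cone_beam_geometry()].
#' @return Scalar cost (`>= 0`).
#' @export
registration_cost <- function(tau, obs, fm, geom) {
  pred <- forward_landmarks(tau, fm, geom, obs$eta_o)
  ok <- attr(pred, "valid") & is.finite(obs$uv[, 1])
  sum(obs$omega[ok] * ((pred[ok, 1] - obs$uv[ok, 1])^2 +
                         (pred[ok, 2] - obs$uv[ok, 2])^2))
}

#' Registration configuration
#'
#' The staged schedule: (1) the projection angle `phi`, (2) the
#' vertical coordinate `y`, (3) the three offsets `x, y, z`, (4) the
#' joint pitches, (5) the orientations `theta, phi`; the outer loop
#' repeats the stages until the largest parameter update or the cost
#' change drops below `tol`.  Stage 1 scans `phi` on a coarse grid
#' before refining, since the projection angle is the one parameter
#' whose zero initialization can sit in the wrong basin (acquisition
#' angles cluster in two opposite ranges).
#'
#' @param tol Convergence tolerance on updates and cost change.
#' @param max_outer Maximum outer iterations.
#' @param bounds Named list of `c(lower, upper)` per parameter
#'   (`x`, `y`, `z`, `theta`, `phi`, `eta`); defaults are twice the
#'   simulated training ranges.
#' @param phi_grid_step Grid step (degrees) of the stage-1 scan.
#' @param z_starts Initial values tried for the depth coordinate `z`:
#'   the full staged schedule is restarted from each and the lowest-cost
#'   solution kept (depth is the weakest-observed parameter from a
#'   single view and can strand the staged descent at a bound).
#' @param stop_cost Restarts stop early once a solution's cost falls
#'   below this value.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(tol = 1e-8, max_outer = 6L,
                                bounds = list(x = c(-360, 360),
                                              y = c(-240, 240),
                                              z = c(-360, 360),
                                              theta = c(-30, 30),
                                              phi = c(-45, 225),
                                              eta = c(-70, 70)),
                                phi_grid_step = 10,
                                z_starts = c(0, -120, 120),
                                stop_cost = 1e-8) {
  stopifnot(tol > 0, max_outer >= 1)
  structure(list(tol = tol, max_outer = as.integer(max_outer),
                 bounds = bounds, phi_grid_step = phi_grid_step,
                 z_starts = z_starts, stop_cost = stop_cost),
            class = "registration_config")
}

# parameter vector layout: x, y, z, theta, phi, eta_1..eta_N
param_names <- function(n_joints)
  c("x", "y", "z", "theta", "phi",
    if (n_joints > 0) paste0("eta_", seq_len(n_joints)))

param_bounds <- function(config, n_joints) {
  b <- config$bounds
  lower <- c(b$x[1], b$y[1], b$z[1], b$theta[1], b$phi[1],
             rep(b$eta[1], n_joints))
  upper <- c(b$x[2], b$y[2], b$z[2], b$theta[2], b$phi[2],
             rep(b$eta[2], n_joints))
  names(lower) <- names(upper) <- param_names(n_joints)
  list(lower = lower, upper = upper)
}

#' Staged least-squares pose reconstruction
#'
#' Recovers the `5 + N` pose vector from weighted 2D landmark
#' observations by the staged schedule of [registration_config()],
#' each stage a bounded Levenberg--Marquardt least-squares solve
#' (numerical Jacobian) over only that stage's parameters, iterated
#' until convergence.  All free parameters start at zero unless an
#' `init` pose is given.  With fewer than 3 landmarks on some joint the
#' rotation stages are refused and a partial (translation-only)
#' estimate is returned.
#'
#' @param obs An [observation_set()].
#' @param fm A [forward_model()].
#' @param geom A [cone_beam_geometry()].
#' @param config A [registration_config()].
#' @param init Optional initial [pose_parameters()].
#' @return An object of class `pose_estimate`: `tau` (the estimate),
#'   `cost`, `converged`, `partial`, `n_outer`, and `trajectory`
#'   (per-stage cost history).
#' @export
register_pose <- function(obs, fm, geom, config = registration_config(),
                          init = NULL) {
  n_joints <- fm$n_joints
  usable <- sum(is.finite(obs$uv[, 1]) & obs$omega > 0)
  if (usable < 6)
    stop("pose not observable: fewer than 6 usable landmarks")
  per_joint <- vapply(seq_len(n_joints), function(i)
    sum(fm$set_id == i & is.finite(obs$uv[, 1])), 0L)
  partial <- any(per_joint < 3)

  nm <- param_names(n_joints)
  v <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(init))
    v[] <- pose_to_vector(init)[c(1, 2, 3, 4, 5, 5 + seq_len(n_joints))]
  bd <- param_bounds(config, n_joints)

  sw <- sqrt(obs$omega)
  resid_fun <- function(full) {
    tau <- pose_parameters(full["x"], full["y"], full["z"],
                           full["theta"], full["phi"],
                           full[grep("^eta_", nm)])
    pred <- forward_landmarks(tau, fm, geom, obs$eta_o)
    r <- cbind(pred[, 1] - obs$uv[, 1], pred[, 2] - obs$uv[, 2]) * sw
    r[!is.finite(r)] <- 1e3          # behind-source guard
    as.numeric(r)
  }
  cost_of <- function(full) sum(resid_fun(full)^2)

  stages <- list("phi", "y", c("x", "y", "z"),
                 grep("^eta_", nm, value = TRUE), c("theta", "phi"))
  rot_stage <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  lm_ctl <- minpack.lm::nls.lm.control(maxiter = 40, ftol = 1e-12,
                                       ptol = 1e-12)
  lm_solve <- function(v0, pars, ctl = lm_ctl) {
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = v0[pars], lower = bd$lower[pars], upper = bd$upper[pars],
      fn = function(sub) { vv <- v0; vv[pars] <- sub; resid_fun(vv) },
      control = ctl))
    v0[pars] <- fit$par
    v0
  }

  run_staged <- function(v) {
    trajectory <- data.frame()
    cost_prev <- cost_of(v)
    converged <- FALSE
    n_outer <- 0L
    for (outer in seq_len(config$max_outer)) {
      n_outer <- outer
      v_prev <- v
      for (si in seq_along(stages)) {
        pars <- stages[[si]]
        if (!length(pars) || (partial && rot_stage[si])) next
        if (si == 1L && outer == 1L) {
          # coarse scan of the projection angle before refining; each
          # candidate angle gets a quick in-plane translation fit so the
          # scan is not blinded by the unknown offsets (depth is left at
          # its start value: fitting it here would collapse the z
          # multi-start diversity into one basin)
          grid <- seq(bd$lower["phi"], bd$upper["phi"],
                      by = config$phi_grid_step)
          qctl <- minpack.lm::nls.lm.control(maxiter = 10)
          best <- v; best_cost <- cost_of(v)   # keep a good init
          for (g in grid) {
            vv <- v; vv["phi"] <- g
            vv <- lm_solve(vv, c("x", "y"), qctl)
            cg <- cost_of(vv)
            if (cg < best_cost) { best_cost <- cg; best <- vv }
          }
          v <- best
        }
        cand <- lm_solve(v, pars)
        if (cost_of(cand) <= cost_of(v)) v <- cand
        trajectory <- rbind(trajectory,
                            data.frame(outer = outer, stage = si,
                                       cost = cost_of(v)))
      }
      cost_now <- cost_of(v)
      if (cost_now <= config$stop_cost ||
          max(abs(v - v_prev)) < config$tol ||
          abs(cost_prev - cost_now) < config$tol) {
        converged <- TRUE
        cost_prev <- cost_now
        break
      }
      cost_prev <- cost_now
    }
    # joint polish over all free parameters: block-coordinate stages can
    # stall on strongly coupled depth/articulation valleys
    free <- if (partial) c("x", "y", "z") else nm
    cand <- lm_solve(v, free,
                     minpack.lm::nls.lm.control(maxiter = 200,
                                                ftol = 1e-14,
                                                ptol = 1e-14))
    if (cost_of(cand) <= cost_prev) {
      v <- cand
      cost_prev <- cost_of(v)
    }
    trajectory <- rbind(trajectory,
                        data.frame(outer = n_outer, stage = 6L,
                                   cost = cost_prev))
    list(v = v, cost = cost_prev, converged = converged,
         n_outer = n_outer, trajectory = trajectory)
  }

  # multi-start over the depth coordinate (weakly observed from a
  # single view); first start at the supplied/zero initialization
  z0s <- if (!is.null(init)) v["z"] else
    unique(c(v["z"], config$z_starts))
  best <- NULL
  for (z0 in z0s) {
    v_try <- v
    v_try["z"] <- z0
    res <- run_staged(v_try)
    prev_best <- if (is.null(best)) Inf else best$cost
    if (is.null(best) || res$cost < best$cost) best <- res
    if (best$cost <= config$stop_cost) break
    # a later start that lands in the same basin adds nothing
    if (is.finite(prev_best) &&
        abs(res$cost - prev_best) <= 0.05 * prev_best) break
  }

  # depth-profile refinement: the depth/articulation valley is narrow
  # and curved, and a Levenberg-Marquardt step pinned at a depth bound
  # cannot slide along it; the profiled cost over z (all other
  # parameters re-fitted) is smooth, so a 1-D search descends it
  if (best$cost > config$stop_cost) {
    free <- if (partial) c("x", "y", "z") else nm
    others <- setdiff(free, "z")
    prof <- new.env(parent = emptyenv())
    prof$v <- best$v
    prof$best_v <- best$v
    prof$best_cost <- best$cost
    pctl <- minpack.lm::nls.lm.control(maxiter = 20)
    profile_cost <- function(z) {
      vv <- prof$v
      vv["z"] <- z
      vv <- lm_solve(vv, others, pctl)
      cc <- cost_of(vv)
      prof$v <- vv                      # warm start the next probe
      if (cc < prof$best_cost) { prof$best_cost <- cc; prof$best_v <- vv }
      cc
    }
    stats::optimize(profile_cost, c(bd$lower["z"], bd$upper["z"]),
                    tol = 1.0)
    if (prof$best_cost < best$cost) {
      cand <- lm_solve(prof$best_v, free,
                       minpack.lm::nls.lm.control(maxiter = 200,
                                                  ftol = 1e-14,
                                                  ptol = 1e-14))
      if (cost_of(cand) < prof$best_cost) {
        prof$best_v <- cand
        prof$best_cost <- cost_of(cand)
      }
      best$v <- prof$best_v
      best$cost <- prof$best_cost
      best$trajectory <- rbind(best$trajectory,
                               data.frame(outer = best$n_outer,
                                          stage = 7L, cost = best$cost))
    }
  }
  v <- best$v
  best$converged <- best$converged || best$cost <= config$stop_cost
  tau <- pose_parameters(v["x"], v["y"], v["z"], v["theta"], v["phi"],
                         v[grep("^eta_", nm)])
  structure(list(tau = tau, cost = best$cost, converged = best$converged,
                 partial = partial, n_outer = best$n_outer,
                 trajectory = best$trajectory),
            class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat(sprintf("<pose_estimate> cost %.4g  %s after %d outer iteration(s)%s\n",
              x$cost, if (x$converged) "converged" else "NOT converged",
              x$n_outer, if (x$partial) " [partial: rotations skipped]" else ""))
  print(x$tau)
  invisible(x)
}

#' Summarize pose-parameter errors
#'
#' Per-parameter absolute errors between estimated and ground-truth
#' poses, with the statistics behind a boxplot: median, quartiles
#' (type-7), whiskers at the most extreme values within 1.5 IQR of the
#' box, and the outliers beyond them.
#'
#' @param estimates List of [pose_parameters()] (or `pose_estimate`s).
#' @param truths List of ground-truth [pose_parameters()].
#' @return A data.frame (one row per parameter: `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `n_outliers`) with the raw
#'   per-trial absolute errors in `attr(, "errors")` and outlier values
#'   in `attr(, "outliers")`.
#' @export
evaluate_errors <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("estimates and truths differ in length")
  est <- lapply(estimates, function(e)
    if (inherits(e, "pose_estimate")) e$tau else e)
  E <- do.call(rbind, lapply(est, pose_to_vector))
  Tm <- do.call(rbind, lapply(truths, pose_to_vector))
  if (ncol(E) != ncol(Tm)) stop("parameter counts differ")
  err <- abs(E - Tm)
  n_joints <- ncol(E) - 5L
  colnames(err) <- c("x", "y", "z", "theta", "phi",
                     if (n_joints > 0) paste0("eta_", seq_len(n_joints)))
  stats_one <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    inside <- v[v >= lo & v <= hi]
    list(median = q[2], q1 = q[1], q3 = q[3],
         whisker_low = min(inside), whisker_high = max(inside),
         outliers = v[v < lo | v > hi])
  }
  st <- apply(err, 2, stats_one)
  out <- do.call(rbind, lapply(names(st), function(nm)
    data.frame(parameter = nm, median = st[[nm]]$median,
               q1 = st[[nm]]$q1, q3 = st[[nm]]$q3,
               whisker_low = st[[nm]]$whisker_low,
               whisker_high = st[[nm]]$whisker_high,
               n_outliers = length(st[[nm]]$outliers))))
  rownames(out) <- NULL
  attr(out, "errors") <- err
  attr(out, "outliers") <- lapply(st, `[[`, "outliers")
  out
}
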