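reg_fixture <- function() {
  if (is.null(.fixture_env$reg)) {
    ref <- ref_fixture()
    cfg <- pipeline_config()
    .fixture_env$reg <- list(
      ref = ref, cfg = cfg,
      fm = forward_model(ref$landmarks$bounding, ref$frames, cfg$fusion,
                         ref$weights))
  }
  .fixture_env$reg
}

test_that("forward landmarks reduce to direct projection at zero pose", {
  rg <- reg_fixture()
  g <- cone_beam_geometry(6550, 10000, 576, 576, binning = 6L)
  tau0 <- pose_parameters(eta_joints = c(0, 0))
  got <- forward_landmarks(tau0, rg$fm, g)
  expect_equal(unname(got[, ]), unname(project_point(g, rg$fm$ref)),
               tolerance = 1e-12)
})

test_that("a landmark deep in one bone moves on a circle under its pitch", {
  rg <- reg_fixture()
  # pick the tibia landmark with the purest tibia weight
  w <- rg$fm$w_ref
  tib <- which(rg$fm$set_id == 2)
  i <- tib[which.max(w[tib, 2] / (rowSums(w[tib, , drop = FALSE]) + 1e-12))]
  O <- rg$ref$frames[[2]]$origin
  p0 <- rg$fm$ref[i, ]
  r0 <- NULL
  for (eta in c(-20, -5, 10, 25)) {
    p <- limbtrack:::articulate_landmarks(rg$fm, c(0, eta))[i, ]
    r <- sqrt(sum((p - O)^2))
    if (is.null(r0)) r0 <- r
    expect_equal(r, r0, tolerance = 1e-6)
  }
})

test_that("the weighted cost has its closed forms", {
  rg <- reg_fixture()
  g <- cone_beam_geometry(6550, 10000, 576, 576, binning = 6L)
  tau <- pose_parameters(5, -3, 10, 2, 8, c(7, -4))
  pred <- forward_landmarks(tau, rg$fm, g)
  # observations equal to the forward projections: zero cost
  obs0 <- observation_set(unclass(pred)[, , drop = FALSE], omega = 1)
  expect_equal(registration_cost(tau, obs0, rg$fm, g), 0)

  # a single (3,4) residual with unit weight costs 25
  uv <- unclass(pred)
  uv[1, ] <- uv[1, ] + c(3, 4)
  expect_equal(registration_cost(tau, observation_set(uv, 1), rg$fm, g),
               25, tolerance = 1e-9)
  # zero-weight landmarks do not contribute
  om <- rep(1, nrow(uv)); om[1] <- 0
  expect_equal(registration_cost(tau, observation_set(uv, om), rg$fm, g),
               0, tolerance = 1e-12)
})

test_that("registration is a fixed point at the ground truth", {
  rg <- reg_fixture()
  g <- cone_beam_geometry(6550, 10000, 576, 576, binning = 6L)
  tau <- pose_parameters(40, -25, 60, 5, 20, c(15, -10))
  uv <- forward_landmarks(tau, rg$fm, g, eta_o = 3)
  obs <- observation_set(uv, 1, eta_o = 3)
  est <- register_pose(obs, rg$fm, g, rg$cfg$registration, init = tau)
  expect_lt(est$cost, 1e-8)
  expect_equal(est$n_outer, 1L)
  expect_true(est$converged)
  expect_lt(max(abs(pose_to_vector(est$tau) - pose_to_vector(tau))),
            1e-4)
})

test_that("the staged solver recovers poses from zero initialization", {
  rg <- reg_fixture()
  rec <- pose_recovery_experiment(rg$ref, rg$cfg, n_trials = 3L,
                                  noise_px = 0, seed = 31L)
  err <- rec$errors
  expect_true(all(err[, c("x", "y", "z")] <= 1))
  expect_true(all(err[, c("theta", "phi", "eta_1", "eta_2")] <= 0.1))
  # monotone improvement: final cost never exceeds the initial cost
  for (e in rec$estimates)
    expect_lte(e$cost, e$trajectory$cost[1] + 1e-9)
})

test_that("shifting all observations shifts the recovered offsets", {
  rg <- reg_fixture()
  g <- cone_beam_geometry(6550, 10000, 576, 576, binning = 6L)
  tau <- pose_parameters(10, 5, 0, 0, 8, c(10, -5))
  uv <- forward_landmarks(tau, rg$fm, g)
  delta <- c(2.0, -1.5)   # binned pixels
  uv2 <- sweep(unclass(uv), 2, delta, "+")
  est <- register_pose(observation_set(uv2, 1), rg$fm, g,
                       rg$cfg$registration, init = tau)
  scale <- g$sod / g$sdd * g$det_pitch * g$binning
  expect_lt(abs((est$tau$x_o - tau$x_o) - delta[1] * scale),
            0.05 * abs(delta[1] * scale))
  expect_lt(abs((est$tau$y_o - tau$y_o) - delta[2] * scale),
            0.05 * abs(delta[2] * scale))
})

test_that("too few landmarks trigger the identifiability guard", {
  rg <- reg_fixture()
  g <- cone_beam_geometry(6550, 10000, 576, 576, binning = 6L)
  # fewer than 6 usable landmarks: not observable at all
  tiny_sets <- lapply(rg$ref$landmarks$bounding, function(s) {
    s$coords <- s$coords[1:2, , drop = FALSE]; s
  })
  fm2 <- forward_model(tiny_sets, rg$ref$frames, rg$cfg$fusion,
                       rg$ref$weights)
  tau <- pose_parameters(eta_joints = c(0, 0))
  uv <- forward_landmarks(tau, fm2, g)
  expect_error(register_pose(observation_set(uv, 1), fm2, g),
               "observable")

  # fewer than 3 per joint: rotations refused, partial estimate
  small_sets <- lapply(rg$ref$landmarks$bounding, function(s) {
    s$coords <- s$coords[1:2, , drop = FALSE]; s
  })
  small_sets[[1]]$coords <- rg$ref$landmarks$bounding[[1]]$coords
  fm3 <- forward_model(small_sets, rg$ref$frames, rg$cfg$fusion,
                       rg$ref$weights)
  tau3 <- pose_parameters(20, -10, 0, eta_joints = c(0, 0))
  uv3 <- forward_landmarks(tau3, fm3, g)
  est3 <- register_pose(observation_set(uv3, 1), fm3, g,
                        rg$cfg$registration)
  expect_true(est3$partial)
  expect_equal(est3$tau$eta_joints, c(0, 0))
})

test_that("evaluate_errors produces textbook boxplot statistics", {
  mk <- function(x) pose_parameters(x, 0, 0, 0, 0)
  ests <- lapply(c(1, 2, 3, 4, 100), mk)
  gts <- lapply(rep(0, 5), mk)
  tab <- evaluate_errors(ests, gts)
  row <- tab[tab$parameter == "x", ]
  expect_equal(row$median, 3)
  expect_equal(row$q1, 2)
  expect_equal(row$q3, 4)
  expect_equal(row$whisker_low, 1)
  expect_equal(row$whisker_high, 4)
  expect_equal(row$n_outliers, 1)
  expect_equal(unname(attr(tab, "outliers")$x), 100)

  # identical estimates: all statistics zero
  z <- evaluate_errors(ests, ests)
  expect_true(all(z$median == 0 & z$q3 == 0 & z$n_outliers == 0))

  # quartiles match an independent percentile computation
  set.seed(55)
  vals <- runif(31, 0, 50)
  tab2 <- evaluate_errors(lapply(vals, mk), lapply(rep(0, 31), mk))
  r2 <- tab2[tab2$parameter == "x", ]
  sv <- sort(vals)
  pct <- function(p) {
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
  }
  expect_equal(r2$median, pct(0.5), tolerance = 1e-12)
  expect_equal(r2$q1, pct(0.25), tolerance = 1e-12)
  expect_equal(r2$q3, pct(0.75), tolerance = 1e-12)

  expect_error(evaluate_errors(ests[1:2], gts), "length")
})
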