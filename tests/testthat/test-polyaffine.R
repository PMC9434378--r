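test_that("rotation_angle matches closed forms and rejects bad input", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(oracle_rotation(c(0, 0, 1), 30 * pi / 180)),
               30 * pi / 180, tolerance = 1e-12)
  set.seed(31)
  ax <- rnorm(3)
  expect_equal(rotation_angle(oracle_rotation(ax, 77 * pi / 180)),
               77 * pi / 180, tolerance = 1e-10)
  expect_error(rotation_angle(matrix(1, 3, 3)), "orthonormal")
})

test_that("log_rotation is antisymmetric and inverts the exponential", {
  expect_equal(log_rotation(diag(3)), matrix(0, 3, 3))
  set.seed(13)
  for (i in 1:100) {
    R <- oracle_rotation(rnorm(3), runif(1, 0.01, 3.0))
    L <- log_rotation(R)
    expect_identical(L, -t(L))
    expect_lt(max(abs(oracle_expm(L) - R)), 1e-10)
  }
  # near-half-turn is outside the log branch
  expect_error(log_rotation(oracle_rotation(c(1, 0, 0), pi - 1e-9)),
               "pi")
})

test_that("fusion weights normalize to one on their support", {
  ref <- ref_fixture()
  w <- ref$weights
  tot <- w$norm[[1]] + w$norm[[2]]
  expect_lt(max(abs(tot[w$support] - 1)), 1e-10)
  expect_true(all(tot[!w$support] == 0))

  # single bone: weight 1 wherever the raw weight clears the support
  w1 <- fusion_weights(ref$seg, 1L, fusion_config(S = 18, sigma_f = 3,
                                                  k_f = 9L))
  expect_lt(max(abs(w1$norm[[1]][w1$support] - 1)), 1e-12)

  # two mirror-symmetric slabs share the mirror plane equally
  d <- c(32L, 16L, 16L)
  lab <- array(0L, d)
  lab[6:12, 5:12, 5:12] <- 1L
  lab[21:27, 5:12, 5:12] <- 2L   # mirror of bone 1 about i = 16.5
  wm <- fusion_weights(label_volume(lab), 1:2,
                       fusion_config(S = 18, sigma_f = 4, k_f = 13L))
  mid <- (wm$norm[[1]][16, 8, 8] + wm$norm[[1]][17, 8, 8]) / 2
  expect_equal(mid, 0.5, tolerance = 1e-6)
})

test_that("fusion_step reduces to the exact exponential and blends", {
  fr <- structure(list(origin = c(3, -2, 1), axes = diag(3), label = 1L),
                  class = "bone_frame")
  cfg <- fusion_config(S = 18, sigma_f = 3, k_f = 9L)

  # zero angles: identity
  m0 <- polyaffine_model(fr, 0, cfg, weights = NULL)
  pts <- matrix(rnorm(30, 0, 10), 10)
  expect_equal(fusion_step(pts, m0), pts)

  # single bone, uniform weight: one step is the exact exponential step
  m1 <- polyaffine_model(fr, 25, cfg, weights = NULL)
  stepped <- fusion_step(pts, m1)
  Rs <- m1$bones[[1]]$R_step
  expected <- sweep(sweep(pts, 2, fr$origin, "-") %*% t(Rs), 2,
                    fr$origin, "+")
  expect_equal(stepped, expected, tolerance = 1e-12)

  # two bones: convex blend per direct evaluation of the fusion formula
  fr2 <- structure(list(origin = c(-5, 4, 0), axes = diag(3), label = 2L),
                   class = "bone_frame")
  m2 <- polyaffine_model(list(fr, fr2), c(25, -10), cfg, weights = NULL)
  w <- cbind(rep(0.3, 10), rep(0.7, 10))
  got <- fusion_step(pts, m2, w = w)
  e1 <- sweep(sweep(pts, 2, fr$origin, "-") %*%
                t(m2$bones[[1]]$R_step), 2, fr$origin, "+") - pts
  e2 <- sweep(sweep(pts, 2, fr2$origin, "-") %*%
                t(m2$bones[[2]]$R_step), 2, fr2$origin, "+") - pts
  expect_equal(got, pts + 0.3 * e1 + 0.7 * e2, tolerance = 1e-12)
})

test_that("S-fold composition of one bone equals the rigid rotation", {
  fr <- structure(list(origin = c(10, 0, -5), axes = diag(3), label = 1L),
                  class = "bone_frame")
  m <- polyaffine_model(fr, 25, fusion_config(S = 18, sigma_f = 3,
                                              k_f = 9L), weights = NULL)
  set.seed(41)
  pts <- matrix(rnorm(60, 0, 20), 20)
  got <- transform_points(pts, m, k = 18)
  R <- m$bones[[1]]$R
  exact <- sweep(sweep(pts, 2, fr$origin, "-") %*% t(R), 2, fr$origin,
                 "+")
  expect_lt(max(abs(got - exact)), 1e-9)

  # zero angles stay put for any k
  m0 <- polyaffine_model(fr, 0, fusion_config(S = 18, sigma_f = 3,
                                              k_f = 9L), weights = NULL)
  expect_equal(transform_points(pts, m0, k = 7), pts)
})

test_that("negated angles with shared weights invert the motion", {
  ref <- ref_fixture()
  cfg <- fusion_config(S = 18, sigma_f = 3, k_f = 9L)
  mdl <- polyaffine_model(ref$frames, c(20, -15), cfg, ref$weights)
  seg <- ref$seg
  d <- dim(seg$data)
  idx <- which(seg$data > 0)
  pts <- sweep(arrayInd(idx, d) - 1, 2, (d - 1) / 2, "-")
  j2 <- ref$phantom$joints$j2
  near <- sqrt(rowSums(sweep(pts, 2, j2, "-")^2)) < 14
  set.seed(3)
  jp <- pts[near, ][sample(sum(near), 150), ]
  w0 <- limbtrack:::eval_weights(mdl, jp)
  fwd <- transform_points(jp, mdl)
  back <- transform_points(fwd, invert_polyaffine(mdl), w = w0)
  expect_lt(max(sqrt(rowSums((back - jp)^2))), 0.1)
})

test_that("doubling the fusion scale barely moves phantom landmarks", {
  ref <- ref_fixture()
  lm <- rbind(ref$landmarks$bounding[[1]]$coords,
              ref$landmarks$bounding[[2]]$coords)
  w <- ref$weights
  a <- transform_points(lm, polyaffine_model(
    ref$frames, c(20, -15), fusion_config(S = 18, sigma_f = 3, k_f = 9L),
    w))
  b <- transform_points(lm, polyaffine_model(
    ref$frames, c(20, -15), fusion_config(S = 36, sigma_f = 3, k_f = 9L),
    w))
  expect_lt(max(sqrt(rowSums((a - b)^2))), 0.05)
})

test_that("the displacement field across the joint has no jumps", {
  ref <- ref_fixture()
  cfg <- fusion_config(S = 18, sigma_f = 3, k_f = 9L)
  eta <- c(15, -12)
  mdl <- polyaffine_model(ref$frames, eta, cfg, ref$weights)
  # sample a line of adjacent voxels crossing the inter-bone region
  j2 <- ref$phantom$joints$j2
  line <- cbind(j2[1], seq(j2[2] - 10, j2[2] + 10, by = 1), j2[3])
  disp <- transform_points(line, mdl) - line
  jumps <- sqrt(rowSums(diff(disp)^2))
  # bound: inter-voxel difference of a rotation by the larger angle at
  # the largest lever arm present in the phantom
  r_max <- max(sqrt(rowSums(sweep(line, 2,
                                  ref$frames[[1]]$origin, "-")^2)))
  bound <- 2 * sin(deg2rad <- max(abs(eta)) * pi / 360) * r_max
  expect_true(all(jumps <= bound))
})

test_that("warp_volume is lattice-exact under the identity model", {
  set.seed(9)
  arr <- array(rnorm(12^3), c(12, 12, 12))
  fr <- structure(list(origin = c(0, 0, 0), axes = diag(3), label = 1L),
                  class = "bone_frame")
  m0 <- polyaffine_model(fr, 0, fusion_config(S = 6, sigma_f = 2,
                                              k_f = 5L), weights = NULL)
  w <- warp_volume(volume(arr), m0)
  expect_equal(w$data, arr, tolerance = 1e-12)
})

test_that("a single-bone warp matches the analytic rotated ball", {
  d <- c(48L, 48L, 48L)
  g <- world_grids(d)
  dist1 <- sqrt((g$X - 6)^2 + g$Y^2 + g$Z^2)
  soft <- pmin(pmax(10.5 - dist1, 0), 1)   # anti-aliased ball, r = 10
  fr <- structure(list(origin = c(0, 0, 0), axes = diag(3), label = 1L),
                  class = "bone_frame")
  m <- polyaffine_model(fr, 20, fusion_config(S = 18, sigma_f = 3,
                                              k_f = 9L), weights = NULL)
  wb <- warp_volume(volume(soft), m)
  ctr <- as.numeric(m$bones[[1]]$R %*% c(6, 0, 0))
  rot <- sqrt((g$X - ctr[1])^2 + (g$Y - ctr[2])^2 +
                (g$Z - ctr[3])^2) <= 10
  wm <- wb$data > 0.5
  expect_gte(sum(wm & rot) / sum(wm | rot), 0.99)
  expect_true(all(is.finite(wb$data)))
  expect_lt(abs(sum(wb$data) / sum(soft) - 1), 0.05)
})

test_that("polyaffine models serialize to JSON", {
  ref <- ref_fixture()
  m <- polyaffine_model(ref$frames, c(12, -8),
                        fusion_config(S = 18, sigma_f = 3, k_f = 9L),
                        ref$weights)
  f <- file.path(tempdir(), "model.json")
  write_polyaffine(m, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$S, 18)
  expect_equal(x$bones$eta_deg, c(12, -8))
})
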