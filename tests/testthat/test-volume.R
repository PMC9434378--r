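# exhaustive between-class-variance argmax over all bin cuts (oracle)
oracle_otsu <- function(v, n_bins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bins <- pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; best_k <- NA
  for (k in seq_len(n_bins - 1L)) {
    lo <- bins <= k
    w0 <- sum(lo); w1 <- sum(!lo)
    if (w0 == 0 || w1 == 0) next
    bcv <- w0 * w1 * (mean(mids[bins[lo]]) - mean(mids[bins[!lo]]))^2
    if (bcv > best + 1e-9) { best <- bcv; best_k <- k }
  }
  edges[best_k + 1L]
}

test_that("otsu_threshold equals the exhaustive between-class oracle", {
  two <- array(rep(c(10, 200), each = 128), c(8, 8, 4))
  thr <- otsu_threshold(two)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_equal(thr, oracle_otsu(two))

  set.seed(5)
  gauss <- array(c(rnorm(1024, 50, 10), rnorm(1024, 200, 10)),
                 c(16, 16, 8))
  thr2 <- otsu_threshold(gauss)
  expect_gt(thr2, 80); expect_lt(thr2, 170)
  expect_equal(thr2, oracle_otsu(gauss))

  expect_error(otsu_threshold(array(3, c(4, 4, 4))), "degenerate")
})

test_that("segment_bones separates, filters, closes and labels", {
  d <- c(40L, 40L, 40L)
  g <- world_grids(d)
  rod1 <- abs(g$X + 10) <= 3 & abs(g$Y) <= 12 & abs(g$Z) <= 3
  rod2 <- abs(g$X - 10) <= 3 & abs(g$Y) <= 9 & abs(g$Z) <= 3
  arr <- array(0.05, d)
  arr[rod1 | rod2] <- 1
  lab <- segment_bones(volume(arr), min_voxels = 30L, close_size = 3L)
  expect_equal(max(lab$data), 2L)
  # labels sorted by descending size
  expect_gt(sum(lab$data == 1L), sum(lab$data == 2L))

  # a tiny speck below min_voxels disappears
  arr2 <- arr
  arr2[2:3, 2:3, 2:3] <- 1     # 8 voxels < 30
  lab2 <- segment_bones(volume(arr2), min_voxels = 30L, close_size = 3L)
  expect_equal(max(lab2$data), 2L)

  # an internal cavity smaller than the closing element is filled;
  # oracle: dilation then erosion of the mask must cover the cavity
  shell <- abs(g$X) <= 6 & abs(g$Y) <= 6 & abs(g$Z) <= 6
  cavity <- abs(g$X) <= 1 & abs(g$Y) <= 1 & abs(g$Z) <= 1
  arr3 <- array(0, d)
  arr3[shell & !cavity] <- 1
  lab3 <- segment_bones(volume(arr3), min_voxels = 30L, close_size = 5L)
  expect_true(all(lab3$data[cavity] > 0))

  # idempotence: re-segmenting the binarized output changes nothing
  relab <- segment_bones(volume(0.0 + (lab3$data > 0)),
                         min_voxels = 30L, close_size = 5L)
  expect_identical(relab$data > 0, lab3$data > 0)

  expect_error(segment_bones(volume(array(c(0, 1e-9),
                                          c(4, 4, 4))),
                             min_voxels = 1e6), "empty")
})

test_that("bone_frame recovers a cylinder's axis and slides the origin", {
  d <- c(40L, 96L, 40L)
  g <- world_grids(d)
  cyl <- (g$X^2 + g$Z^2 <= 64) & abs(g$Y) <= 40
  # asymmetric cap so the frame is unambiguous
  cap <- (g$X^2 + (g$Y - 40)^2 + g$Z^2) <= 36
  lab <- label_volume(array(as.integer(cyl | cap), d))
  fr <- bone_frame(lab, 1L, end_hint = 1)
  ang <- acos(abs(sum(fr$axes[, 2] * c(0, 1, 0)))) * 180 / pi
  expect_lt(ang, 2)

  # eigenvalues equal a direct covariance computation
  idx <- which(lab$data == 1L, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, (d - 1) / 2, "-")
  ev <- sort(eigen(cov(pts), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(fr$eigenvalues, ev, tolerance = 1e-10)

  # orthonormal axes
  expect_lt(max(abs(crossprod(fr$axes) - diag(3))), 1e-10)

  # origin displaced from CoM along +e_y by exactly 2 sqrt(sigma_max)
  expect_equal(fr$origin, fr$com + 2 * sqrt(fr$eigenvalues[1]) *
                 fr$axes[, 2], tolerance = 1e-12)

  # a ball has no preferred axis
  ball <- label_volume(array(as.integer(g$X^2 + g$Y^2 + g$Z^2 <= 100), d))
  expect_error(bone_frame(ball, 1L), "ambiguous")
})

test_that("tricubic interpolation reproduces cubics and is linear", {
  d <- c(16L, 16L, 16L)
  g <- world_grids(d)
  f <- function(x, y, z) x^3 + 2 * y^2 * z - z
  v <- volume(f(g$X, g$Y, g$Z))

  # exact on the lattice
  set.seed(2)
  idx <- cbind(sample(3:14, 20, TRUE), sample(3:14, 20, TRUE),
               sample(3:14, 20, TRUE))
  wpts <- sweep(idx - 1, 2, (d - 1) / 2, "-")
  expect_equal(tricubic_interpolate(v, wpts),
               f(wpts[, 1], wpts[, 2], wpts[, 3]), tolerance = 1e-12)

  # exact off the lattice for a 3rd-order polynomial
  pts <- cbind(runif(30, -4, 4), runif(30, -4, 4), runif(30, -4, 4))
  expect_equal(tricubic_interpolate(v, pts),
               f(pts[, 1], pts[, 2], pts[, 3]), tolerance = 1e-8)

  # constant volume reproduces the constant
  expect_equal(tricubic_interpolate(volume(array(7, d)), pts),
               rep(7, 30), tolerance = 1e-12)

  # linearity in the volume values
  set.seed(3)
  v1 <- array(rnorm(prod(d)), d); v2 <- array(rnorm(prod(d)), d)
  lhs <- tricubic_interpolate(volume(2.5 * v1 + 1.5 * v2), pts)
  rhs <- 2.5 * tricubic_interpolate(v1, pts) +
    1.5 * tricubic_interpolate(v2, pts)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("label_components6 honors face connectivity", {
  d <- c(8L, 8L, 8L)
  m <- array(FALSE, d)
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE        # diagonal neighbor: separate component
  m[2, 3, 2] <- TRUE        # face neighbor of (2,2,2)
  lab <- label_components6(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2, 2], lab[2, 3, 2])
  expect_true(lab[3, 3, 3] != lab[2, 2, 2])
})
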