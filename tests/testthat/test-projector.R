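test_that("projection integrates attenuation along source rays", {
  # empty volume projects to zero
  g <- cone_beam_geometry(6000, 9000, 48, 48, det_pitch = 1, binning = 1L)
  expect_equal(max(project_volume(volume(array(0, c(16, 16, 16))),
                                  g)$image), 0)

  # a bright voxel's image peak sits at its point projection
  arr <- array(0, c(33, 33, 33)); arr[17, 21, 17] <- 1
  r <- project_volume(volume(arr), g)
  peak <- which(r$image == max(r$image), arr.ind = TRUE)[1, ]
  uv <- project_point(g, c(0, 4, 0))
  rc <- detector_to_pixel(uv, dim(r$image))
  expect_lt(max(abs(peak - rc)), 1)

  # the central ray through a unit cube integrates its chord length
  g2 <- cone_beam_geometry(6000, 9000, 60, 60, det_pitch = 1,
                           binning = 6L)
  r2 <- project_volume(volume(array(1, c(20, 20, 20))), g2)
  centre <- r2$image[5, 5]
  expect_lt(abs(centre - 20) / 20, 0.02)

  # linearity and monotonicity in the volume
  set.seed(4)
  v1 <- array(runif(16^3), c(16, 16, 16))
  v2 <- array(runif(16^3), c(16, 16, 16))
  p1 <- project_volume(volume(v1), g2)$image
  p12 <- project_volume(volume(v1 + v2), g2)$image
  expect_equal(p12, p1 + project_volume(volume(v2), g2)$image,
               tolerance = 1e-10)
  expect_true(all(p12 >= p1 - 1e-12))
})

test_that("mask projection covers the projected 3D landmarks", {
  ref <- ref_fixture()
  g <- cone_beam_geometry(6550, 10000, 576, 576, det_pitch = 1,
                          binning = 6L)
  pose <- pose_parameters(phi_o = 15)
  for (b in 1:2) {
    mk <- project_mask(ref$seg, b, g, pose)
    lm2 <- project_point(g, apply_rigid(pose,
                                        ref$landmarks$bounding[[b]]$coords))
    rc <- round(detector_to_pixel(lm2, dim(mk)))
    # every ground-truth landmark projects onto (or within 1 px of) it
    near <- vapply(seq_len(nrow(rc)), function(i) {
      rr <- max(1, rc[i, 1] - 1):min(nrow(mk), rc[i, 1] + 1)
      cc <- max(1, rc[i, 2] - 1):min(ncol(mk), rc[i, 2] + 1)
      any(mk[rr, cc])
    }, TRUE)
    expect_true(all(near))
  }
  # union of bones equals union of per-bone masks
  mku <- project_mask(ref$seg, 1:2, g, pose)
  expect_identical(mku, project_mask(ref$seg, 1, g, pose) |
                     project_mask(ref$seg, 2, g, pose))
  # a bone fully outside the field of view projects to nothing
  far <- pose_parameters(x_o = 5e3)
  expect_equal(sum(project_mask(ref$seg, 1, g, far)), 0)
})

test_that("Poisson noise scales to I0 and is seed-deterministic", {
  set.seed(8)
  img <- matrix(runif(64, 0.2, 1), 8)
  scaled_max <- max(img) * (2000 / max(img))
  expect_equal(scaled_max, 2000)
  n1 <- add_poisson_noise(img, 2000, seed = 3)
  n2 <- add_poisson_noise(img, 2000, seed = 3)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_poisson_noise(img, 2000, seed = 4)))

  # a pixel with scaled mean 100 averages to 100 over many draws
  one <- matrix(c(100, 50), 1)    # max 100 -> I0 100 keeps means
  draws <- vapply(1:10000, function(s)
    add_poisson_noise(one, 100, seed = s)[1, 1], 0)
  expect_gt(mean(draws), 99); expect_lt(mean(draws), 101)

  expect_error(add_poisson_noise(matrix(0, 2, 2), 100), "zero")
})

test_that("manifest enumeration reproduces the campaign sizes", {
  tp <- training_plan()
  expect_equal(prod(lengths(tp$articulation_grids)), 30)
  m <- build_manifest(tp)
  expect_equal(nrow(m), 15600)
  expect_equal(length(unique(m$vol_id)), 30)
  expect_equal(as.integer(table(m$split)[c("train", "val", "test")]),
               c(11700, 3120, 780))

  sp <- study_plan()
  expect_equal(prod(lengths(sp$articulation_grids)), 9)
  expect_equal(length(sp$interval_centers), 8)

  tiny <- acquisition_plan(list(a = 0), 0, 1, 1L)
  expect_equal(nrow(build_manifest(tiny)), 1)

  # jitters honor their ranges and are seed-deterministic
  expect_true(all(abs(m$theta) <= tp$theta_range))
  expect_true(all(m$sod >= tp$sod[1] - tp$sod[2] &
                    m$sod <= tp$sod[1] + tp$sod[2]))
  expect_identical(m, build_manifest(tp))
})

test_that("generated samples carry self-consistent ground truth", {
  ref <- ref_fixture()
  plan <- acquisition_plan(
    articulation_grids = list(j1 = c(-10, 15), j2 = c(5)),
    interval_centers = c(0, 180), interval_half_width = 3,
    n_projections = 1L, xyz_range = c(30, 20, 30), seed = 7L)
  manifest <- build_manifest(plan)
  sets <- ref$landmarks$bounding
  samples <- generate_dataset(manifest, ref$phantom$volume, ref$seg,
                              ref$frames, sets,
                              fusion_config(S = 18, sigma_f = 3, k_f = 9L),
                              det = c(576L, 576L), binning = 6L,
                              render = "none", weights = ref$weights)
  expect_length(samples, nrow(manifest))
  for (s in samples[1:2]) {
    for (b in 1:2) {
      redo <- project_point(s$geom,
                            apply_rigid(s$pose, s$landmarks3d_posed[[b]],
                                        s$eta_o))
      expect_equal(s$landmarks2d[[b]], redo, tolerance = 1e-6)
    }
  }
  # determinism
  samples2 <- generate_dataset(manifest, ref$phantom$volume, ref$seg,
                               ref$frames, sets,
                               fusion_config(S = 18, sigma_f = 3,
                                             k_f = 9L),
                               det = c(576L, 576L), binning = 6L,
                               render = "none", weights = ref$weights)
  expect_equal(samples[[1]]$landmarks2d, samples2[[1]]$landmarks2d)
})

test_that("plans round-trip through YAML", {
  tp <- training_plan(seed = 3L)
  f <- file.path(tempdir(), "plan.yaml")
  write_plan(tp, f)
  back <- read_plan(f)
  expect_equal(back$interval_centers, tp$interval_centers)
  expect_equal(back$sod, tp$sod)
  expect_equal(nrow(build_manifest(back)), 15600)
})
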