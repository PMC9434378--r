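test_that("encoded vector fields are unit norm and collinear", {
  mask <- disk_mask()
  lm <- c(27.3, 21.8)
  f <- encode_vector_field(mask, lm)
  idx <- which(mask, arr.ind = TRUE)
  vr <- f[cbind(idx, 1L)]; vc <- f[cbind(idx, 2L)]
  nrm <- sqrt(vr^2 + vc^2)
  expect_true(all(abs(nrm - 1) < 1e-12 | nrm == 0))
  # collinearity: the landmark lies on p + t v, t >= 0
  t_land <- (lm[1] - idx[, 1]) * vr + (lm[2] - idx[, 2]) * vc
  res <- abs((lm[1] - idx[, 1]) * vc - (lm[2] - idx[, 2]) * vr)
  expect_true(all(res < 1e-12))
  expect_true(all(t_land >= 0))
  # zero outside the mask
  expect_equal(sum(f[cbind(which(!mask, arr.ind = TRUE), 1L)]^2), 0)
  # single-pixel mask at the landmark: zero field
  m1 <- matrix(FALSE, 8, 8); m1[4, 4] <- TRUE
  expect_equal(max(abs(encode_vector_field(m1, c(4, 4)))), 0)
})

test_that("voting recovers the landmark from exact and corrupted fields", {
  set.seed(11)
  for (trial in 1:10) {
    centre <- runif(2, 16, 32); rad <- runif(1, 6, 12)
    mask <- disk_mask(c(48L, 48L), centre, rad)
    lm <- centre + runif(2, -rad / 2, rad / 2)
    f <- encode_vector_field(mask, lm)
    v <- vote_landmark(f, mask, voting_config(seed = trial))
    expect_lt(sqrt(sum((v$mu_hat - lm)^2)), 0.5)
    expect_lte(v$sigma, 0.5)
    expect_gt(v$omega, 0)
  }
  # 20% of vectors replaced by random directions
  for (trial in 1:10) {
    mask <- disk_mask(); lm <- c(27, 22)
    f <- encode_vector_field(mask, lm)
    idx <- which(mask, arr.ind = TRUE)
    set.seed(100 + trial)
    bad <- sample(nrow(idx), round(0.2 * nrow(idx)))
    ang <- runif(length(bad), 0, 2 * pi)
    f[cbind(idx[bad, ], 1L)] <- cos(ang)
    f[cbind(idx[bad, ], 2L)] <- sin(ang)
    v <- vote_landmark(f, mask, voting_config(seed = trial))
    expect_lt(sqrt(sum((v$mu_hat - lm)^2)), 1)
  }
  # degenerate inputs
  m1 <- matrix(FALSE, 8, 8); m1[4, 4] <- TRUE
  expect_error(vote_landmark(array(0, c(8, 8, 2)), m1, voting_config()),
               "degenerate")
  # all-parallel field
  mp <- matrix(TRUE, 4, 4)
  fp <- array(0, c(4, 4, 2)); fp[, , 1] <- 1
  expect_error(vote_landmark(fp, mp, voting_config(seed = 1)),
               "degenerate|parallel")
})

test_that("voting error degrades gracefully with corruption", {
  fracs <- c(0, 0.1, 0.2, 0.4)
  med <- vapply(fracs, function(fr) {
    errs <- vapply(1:20, function(trial) {
      mask <- disk_mask(); lm <- c(27, 22)
      f <- encode_vector_field(mask, lm)
      if (fr > 0) {
        idx <- which(mask, arr.ind = TRUE)
        set.seed(1000 * fr + trial)
        bad <- sample(nrow(idx), round(fr * nrow(idx)))
        ang <- runif(length(bad), 0, 2 * pi)
        f[cbind(idx[bad, ], 1L)] <- cos(ang)
        f[cbind(idx[bad, ], 2L)] <- sin(ang)
      }
      v <- vote_landmark(f, mask, voting_config(seed = trial))
      sqrt(sum((v$mu_hat - lm)^2))
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med) >= -1e-9))
})

test_that("the network emits full-resolution fields and segments", {
  cfg <- bonenet_config(input_size = 32L, k = 3L,
                        widths = c(4L, 8L, 8L, 8L), stem_width = 4L,
                        decoder_width = 8L)
  net <- build_bonenet(cfg, seed = 2)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2, 1))
  fw <- bonenet_forward(net, x)
  expect_equal(dim(fw$fields), c(32, 32, 2, 6))
  expect_equal(dim(fw$seg), c(32, 32, 2, 2))
  expect_error(bonenet_config(input_size = 50L), "divisible")

  # the deepened stack [3,3,4,3] has exactly 5 more blocks and strictly
  # more parameters than the baseline [2,2,2,2]
  expect_equal(sum(cfg$depths) - sum(c(2, 2, 2, 2)), 5)
  base <- build_bonenet(bonenet_config(input_size = 32L, k = 3L,
                                       depths = c(2L, 2L, 2L, 2L),
                                       widths = c(4L, 8L, 8L, 8L),
                                       stem_width = 4L,
                                       decoder_width = 8L), seed = 2)
  expect_gt(count_params(net), count_params(base))
})

test_that("the loss has its closed forms and masking contract", {
  d <- c(8L, 8L, 1L, 2L)
  fields <- array(0, d); target <- array(0, d)
  seg <- array(0, c(8, 8, 1, 2))
  mask <- matrix(FALSE, 8, 8); mask[4, 5] <- TRUE

  # perfect prediction: zero field term, cross entropy at its minimum
  seg_perf <- seg; seg_perf[, , 1, 1] <- 50; seg_perf[4, 5, 1, ] <- c(0, 50)
  l0 <- bonenet_loss(fields, seg_perf, target, mask)
  expect_equal(l0$field_term, 0)
  expect_lt(l0$ce_term, 1e-8)

  # one masked pixel with residual (0.5, 0): Huber gives 0.125
  f1 <- fields; f1[4, 5, 1, 1] <- 0.5
  l1 <- bonenet_loss(f1, seg_perf, target, mask)
  expect_equal(l1$field_term, 0.125)

  # perturbing unmasked pixels changes nothing
  f2 <- f1
  f2[1, 1, 1, ] <- 99; f2[8, 8, 1, ] <- -99
  expect_equal(bonenet_loss(f2, seg_perf, target, mask)$field_term,
               l1$field_term)

  # subtractive sign convention is available
  lm <- bonenet_loss(f1, seg, target, mask, ce_sign = -1)
  lp <- bonenet_loss(f1, seg, target, mask, ce_sign = 1)
  expect_equal(lp$total + lm$total, 2 * lp$field_term)
})

test_that("loss gradients match numerical differentiation", {
  set.seed(21)
  d <- c(8L, 8L, 1L, 4L)
  fields <- array(rnorm(prod(d)), d)
  target <- array(rnorm(prod(d)), d)
  seg <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  mask <- matrix(runif(64) > 0.4, 8, 8)
  l <- bonenet_loss(fields, seg, target, mask, grad = TRUE)
  h <- 1e-6
  for (i in sample(prod(d), 5)) {
    fp <- fields; fp[i] <- fp[i] + h
    fm <- fields; fm[i] <- fm[i] - h
    num <- (bonenet_loss(fp, seg, target, mask)$total -
              bonenet_loss(fm, seg, target, mask)$total) / (2 * h)
    expect_equal(l$dfields[i], num, tolerance = 1e-4)
  }
  for (i in sample(length(seg), 5)) {
    sp <- seg; sp[i] <- sp[i] + h
    sm <- seg; sm[i] <- sm[i] - h
    num <- (bonenet_loss(fields, sp, target, mask)$total -
              bonenet_loss(fields, sm, target, mask)$total) / (2 * h)
    expect_equal(l$dseg[i], num, tolerance = 1e-4)
  }
})

test_that("network training reduces the loss deterministically", {
  samples <- lapply(1:4, toy_detection_sample, size = 32L, k = 2L)
  cfg <- bonenet_config(input_size = 32L, k = 2L,
                        widths = c(4L, 8L, 8L, 8L), stem_width = 4L,
                        decoder_width = 8L)
  tc <- train_config(base_lr = 2e-3, decay_epochs = 0L, max_epochs = 4L,
                     batch_size = 2L, seed = 5L)
  r1 <- train_bonenet(samples, build_bonenet(cfg, seed = 7), tc)
  expect_lt(tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  r2 <- train_bonenet(samples, build_bonenet(cfg, seed = 7), tc)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
})

test_that("encode-vote round trips stay within half a pixel", {
  set.seed(33)
  worst <- 0
  for (trial in 1:50) {
    centre <- runif(2, 14, 34); rad <- runif(1, 5, 12)
    mask <- disk_mask(c(48L, 48L), centre, rad)
    lm <- centre + runif(2, -rad * 0.6, rad * 0.6)
    f <- encode_vector_field(mask, lm)
    v <- vote_landmark(f, mask, voting_config(seed = trial))
    worst <- max(worst, sqrt(sum((v$mu_hat - lm)^2)))
  }
  expect_lt(worst, 0.5)
})
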