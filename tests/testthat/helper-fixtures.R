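# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# the default desk-scale phantom with its full reference chain
ref_fixture <- function() {
  if (is.null(.fixture_env$ref))
    .fixture_env$ref <- build_reference(pipeline_config(seed = 1L))
  .fixture_env$ref
}

# independent Rodrigues-formula rotation (test oracle; kept separate
# from the package's rotation_about_axis on purpose: different algebra)
oracle_rotation <- function(axis, angle_rad) {
  n <- axis / sqrt(sum(axis^2))
  x <- n[1]; y <- n[2]; z <- n[3]
  c <- cos(angle_rad); s <- sin(angle_rad); C <- 1 - c
  matrix(c(x * x * C + c,     x * y * C + z * s, x * z * C - y * s,
           y * x * C - z * s, y * y * C + c,     y * z * C + x * s,
           z * x * C + y * s, z * y * C - x * s, z * z * C + c),
         3, 3, byrow = FALSE)
}

# matrix exponential by eigendecomposition (oracle)
oracle_expm <- function(L) {
  e <- eigen(L)
  Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
}

# world coordinate grids of a given shape
world_grids <- function(d) {
  cx <- seq_len(d[1]) - 1 - (d[1] - 1) / 2
  cy <- seq_len(d[2]) - 1 - (d[2] - 1) / 2
  cz <- seq_len(d[3]) - 1 - (d[3] - 1) / 2
  list(X = array(rep(cx, times = d[2] * d[3]), d),
       Y = array(rep(rep(cy, each = d[1]), times = d[3]), d),
       Z = array(rep(cz, each = d[1] * d[2]), d))
}

# a circular 2D mask and encoded field around a landmark
disk_mask <- function(d = c(48L, 48L), centre = c(24, 24), radius = 10) {
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1]))
    mask[i, ] <- (i - centre[1])^2 + (seq_len(d[2]) - centre[2])^2 <=
      radius^2
  mask
}

# small synthetic detection training sample (disk + landmarks)
toy_detection_sample <- function(seed, size = 64L, k = 4L) {
  set.seed(seed)
  cr <- runif(2, 0.3 * size, 0.7 * size)
  rad <- runif(1, 0.12 * size, 0.2 * size)
  mask <- disk_mask(c(size, size), cr, rad)
  img <- matrix(rnorm(size * size, 10, 1), size) + 30 * mask
  lms <- cbind(cr[1] + runif(k, -rad / 2, rad / 2),
               cr[2] + runif(k, -rad / 2, rad / 2))
  make_training_sample(img, mask, lms)
}
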