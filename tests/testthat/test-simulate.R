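test_that("phantoms are reproducible and bead centers are recoverable", {
  v1 <- make_phantom("beads", c(32L, 32L, 32L), 10L, seed = 1L)
  v2 <- make_phantom("beads", c(32L, 32L, 32L), 10L, seed = 1L)
  expect_identical(unclass(v1), unclass(v2))
  expect_true(all(v1 >= 0) && all(is.finite(v1)))
  expect_error(make_phantom("beads", c(32L, 32L, 32L), 0L), "positive")
  expect_error(make_phantom("beads", c(8L, 32L, 32L), 4L), ">= 16")
  # local maxima sit on the generated centers (within a voxel)
  ctr <- attr(v1, "centers")
  for (i in seq_len(nrow(ctr))) {
    c0 <- round(ctr[i, ])
    win <- v1[max(1, c0[1] - 2):min(32, c0[1] + 2),
              max(1, c0[2] - 2):min(32, c0[2] + 2),
              max(1, c0[3] - 2):min(32, c0[3] + 2)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_true(all(abs(pk - 3) <= 1))   # window center = 3 when interior
  }
})

test_that("the geometric projector shifts views by the analytic disparity", {
  proj <- lf_projector(c(5L, 5L), 9L, kappa = 0.5)
  # focal-plane voxel: identical across views
  vol <- array(0, c(9, 21, 21)); vol[5, 11, 11] <- 1
  lf <- project_volume(vol, proj)
  for (u in 1:5) for (v in 1:5)
    expect_equal(lf$data[u, v, , ], lf$data[3, 3, , ], tolerance = 1e-12)
  # off-focus voxel: per-view centroid displaced by d(z) * (v - v0, u - u0)
  vol2 <- array(0, c(9, 21, 21)); vol2[7, 11, 11] <- 1
  lf2 <- project_volume(vol2, proj)
  d <- disparity_at(proj, 7)
  for (u in c(1L, 4L)) for (v in c(2L, 5L)) {
    img <- lf2$data[u, v, , ]
    cy <- sum(row(img) * img) / sum(img)
    cx <- sum(col(img) * img) / sum(img)
    expect_equal(cy - 11, d * (v - 3), tolerance = 1e-9)
    expect_equal(cx - 11, d * (u - 3), tolerance = 1e-9)
  }
  # linearity
  a <- make_phantom("beads", c(16L, 20L, 20L), 3L, seed = 2L)
  b <- make_phantom("beads", c(16L, 20L, 20L), 3L, seed = 3L)
  pr <- lf_projector(c(3L, 3L), 16L, kappa = 0.2)
  lin <- project_volume(2 * a + 3 * b, pr)
  sep <- 2 * project_volume(a, pr)$data + 3 * project_volume(b, pr)$data
  expect_equal(lin$data, sep, tolerance = 1e-10)
})

test_that("per-view flux is conserved for in-bounds shifts", {
  vol <- array(0, c(9, 31, 31))
  vol[ , 12:20, 12:20] <- 1          # content away from the border
  proj <- lf_projector(c(3L, 3L), 9L, kappa = 0.3)
  lf <- project_volume(vol, proj)
  total <- sum(vol)
  for (u in 1:3) for (v in 1:3)
    expect_lt(abs(sum(lf$data[u, v, , ]) - total) / total, 0.01)
})

test_that("the camera model scales to the photon budget and is Poisson-Gaussian", {
  clean <- lightfield(array(runif(3 * 1 * 10 * 10, 0.2, 1), c(3, 1, 10, 10)))
  np <- noise_params(photon_max = 100, gauss_var = 5, seed = 2L)
  out <- corrupt(clean, np)
  expect_equal(max(out$clean_scaled$data), 100)
  expect_true(all(out$noisy$data >= 0 & out$noisy$data <= 65535))
  expect_true(all(out$noisy$data == round(out$noisy$data)))
  # reproducibility
  out2 <- corrupt(clean, np)
  expect_identical(out$noisy$data, out2$noisy$data)
  # noiseless limit: large photon budget (within the 16-bit range), no read noise
  np0 <- noise_params(photon_max = 6e4, gauss_sigma = 0, seed = 3L)
  o0 <- corrupt(clean, np0)
  rel <- sqrt(mean((o0$noisy$data - o0$clean_scaled$data)^2)) / mean(o0$clean_scaled$data)
  expect_lt(rel, 0.01)
  expect_error(corrupt(lightfield(array(0, c(2, 1, 4, 4))), np), "zero")
})

test_that("Monte-Carlo mean and variance match the Poisson-Gaussian model", {
  # constant field: every pixel has expectation photon_max after scaling
  n <- 10000L
  clean <- lightfield(array(1, c(1, 1, 100, 100)))
  np <- noise_params(photon_max = 100, gauss_var = 5, seed = 4L)
  noisy <- corrupt(clean, np)$noisy$data
  expect_gte(mean(noisy), 99)
  expect_lte(mean(noisy), 101)
  # Var = lambda + sigma^2 (+ 1/12 quantization), within MC tolerance
  expect_gt(stats::var(as.vector(noisy)[seq_len(n)]), 95)
  expect_lt(stats::var(as.vector(noisy)[seq_len(n)]), 115)
})

test_that("joint spatial-angular flips commute with the projector", {
  vol <- make_phantom("beads", c(16L, 24L, 24L), 4L, seed = 9L)
  proj <- lf_projector(c(3L, 3L), 16L, kappa = 0.25)
  lf <- project_volume(vol, proj)
  vol_fx <- vol[, , rev(seq_len(24))]          # mirror x
  lf_fx <- project_volume(vol_fx, proj)
  expect_equal(lf_fx$data, lf_augment(lf$data, 1L), tolerance = 1e-10)
  vol_fy <- vol[, rev(seq_len(24)), ]          # mirror y
  lf_fy <- project_volume(vol_fy, proj)
  expect_equal(lf_fy$data, lf_augment(lf$data, 2L), tolerance = 1e-10)
})
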