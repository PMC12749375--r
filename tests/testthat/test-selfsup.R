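test_that("parity splitting partitions the parent and recombines bit-exactly", {
  set.seed(21)
  epi <- array(runif(128 * 81 * 16), c(128, 81, 16))  # narrow inner axis for speed
  pr <- split_substack_pair(epi, parity = 0L)
  expect_equal(dim(pr$input), c(64, 81, 16))
  expect_equal(dim(pr$target), c(64, 81, 16))
  expect_identical(recombine_substack_pair(pr), epi)
  pr1 <- split_substack_pair(epi, parity = 1L)
  expect_identical(recombine_substack_pair(pr1), epi)
  # disjoint and exhaustive: values of input+target equal the parent multiset
  expect_identical(sort(c(pr$input, pr$target)), sort(as.vector(epi)))
  # constant parent: input == target
  prc <- split_substack_pair(array(7, c(8, 4, 4)), parity = 0L)
  expect_identical(prc$input, prc$target)
  expect_error(split_substack_pair(array(0, c(7, 4, 4)), 0L), "even")
})

test_that("mask pairs are disjoint edge-adjacent 2-of-4 gathers, constant over views", {
  pt <- mask_patterns()
  expect_equal(dim(pt), c(8L, 2L))
  expect_true(all(pt[, 1] != pt[, 2]))
  off <- lfdenoise:::.cell_offsets
  for (i in 1:8) {       # edge-adjacent: offsets differ in exactly one axis
    d <- abs(off[pt[i, 1], ] - off[pt[i, 2], ])
    expect_equal(sum(d), 1L)
  }
  set.seed(22)
  mp <- sample_mask_pair(c(128L, 128L))
  expect_equal(length(mp$m1), 64L * 64L)
  expect_true(length(intersect(mp$m1, mp$m2)) == 0L)   # pixel-disjoint
  # applying the masks to a unique-valued patch gathers disjoint subsets
  patch <- array(seq_len(5 * 16 * 16), c(5, 16, 16))
  mp2 <- sample_mask_pair(c(16L, 16L))
  o1 <- apply_mask(patch, mp2$m1)
  o2 <- apply_mask(patch, mp2$m2)
  expect_equal(dim(o1), c(5L, 8L, 8L))
  expect_true(all(o1 %in% patch))                       # pure gather
  expect_equal(length(intersect(o1, o2)), 0L)
  # same gather at every angular view
  for (a in 2:5) {
    expect_identical(o1[a, , ] - o1[1, , ],
                     array(patch[a, 1, 1] - patch[1, 1, 1], c(8, 8)))
  }
  # constant patch stays constant
  oc <- apply_mask(array(4, c(2, 8, 8)), sample_mask_pair(c(8L, 8L))$m1)
  expect_true(all(oc == 4))
  expect_error(sample_mask_pair(c(7L, 8L)), "even")
})

test_that("the eight mask patterns are drawn uniformly", {
  set.seed(23)
  n <- 8000L
  draws <- integer(0)
  for (i in seq_len(n / 4)) {
    draws <- c(draws, as.vector(sample_mask_pair(c(4L, 4L))$pattern_grid))
  }
  counts <- tabulate(draws, 8L)
  expect_equal(sum(counts), n)
  sigma <- sqrt(n * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - n / 8) < 3 * sigma + 1))
})

test_that("dihedral augmentation keeps angular and spatial axes consistent", {
  patch <- array(runif(3 * 3 * 6 * 6), c(3, 3, 6, 6))
  expect_identical(lf_augment(patch, 0L), patch)
  expect_identical(lf_augment(lf_augment(patch, 1L), 1L), patch)  # involution
  expect_identical(lf_augment(lf_augment(patch, 2L), 2L), patch)
  expect_identical(lf_augment(lf_augment(patch, 4L), 4L), patch)
  expect_error(lf_augment(array(0, c(2, 3, 4, 4)), 4L), "square")
})

test_that("training sets are reproducible and within bounds", {
  sim <- tiny_sim()
  t1 <- build_training_set(list(sim$noisy), n_patches = 1000L, patch_size = 16L, seed = 3L)
  t2 <- build_training_set(list(sim$noisy), n_patches = 1000L, patch_size = 16L, seed = 3L)
  expect_equal(nrow(t1$samples), 1000L)
  expect_identical(t1$samples, t2$samples)
  sp <- spatial_shape(sim$noisy)
  expect_true(all(t1$samples$y0 >= 1 & t1$samples$y0 + 15L <= sp[1]))
  expect_true(all(t1$samples$x0 >= 1 & t1$samples$x0 + 15L <= sp[2]))
  s <- get_training_sample(t1, 17L)
  expect_equal(dim(s$patch), c(3L, 3L, 16L, 16L))
  expect_lte(max(s$patch), 1)
  expect_error(build_training_set(list(), 10L), "at least one")
  few <- lightfield(array(0, c(2, 2, 32, 32)))
  expect_error(build_training_set(list(few), 10L, patch_size = 16L), "8 angular")
})
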