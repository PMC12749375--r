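ns <- asNamespace("lfdenoise")

test_that("central view selection keeps the centered sub-grid", {
  lf <- lightfield(array(runif(13 * 13 * 6 * 6), c(13, 13, 6, 6)))
  out <- select_central_views(lf, 9L)
  expect_equal(unname(angular_shape(out)), c(9L, 9L))
  expect_equal(n_views(out), 81L)
  # 0-based rows/cols 2..10 of the 13-grid, i.e. 1-based 3..11
  expect_identical(out$data, lf$data[3:11, 3:11, , ])
  # identity on an already-9x9 stack, and idempotent
  expect_identical(select_central_views(out, 9L), out)
  expect_error(select_central_views(lf, 8L), "odd")
  expect_error(select_central_views(lf, 15L), "exceeds")
  lfr <- lightfield(array(0, c(13, 9, 4, 4)))
  expect_error(select_central_views(lfr, 9L), "square")
})

test_that("angular padding replicates views, flags them, and strips bit-exactly", {
  lf <- lightfield(array(runif(13 * 1 * 5 * 5), c(13, 1, 5, 5)), system_tag = "2pSAM")
  out <- pad_angular_views(lf, 16L)
  expect_equal(n_views(out), 16L)
  expect_equal(sum(out$pad_flags), 3L)
  expect_identical(strip_padded_views(out)$data, lf$data)
  lf16 <- lightfield(array(runif(16 * 1 * 5 * 5), c(16, 1, 5, 5)))
  expect_identical(pad_angular_views(lf16, 16L), lf16)
  lf20 <- lightfield(array(0, c(20, 1, 5, 5)))
  expect_error(pad_angular_views(lf20, 16L), "exceeds")
})

test_that("EPI traversal matches the hand-enumerated order on a 2x2 toy field", {
  lf <- coded_lightfield(2L, 2L, 2L, 2L)
  # serpentine x-s: u fastest, direction alternating per v row
  exs <- lf_to_epi_stack(lf, "x-s")
  expect_equal(dim(exs$data), c(2L, 4L, 2L))
  want <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))
  expect_equal(unname(exs$traversal), unname(want))
  for (a in 1:4) for (y in 1:2) for (x in 1:2)
    expect_equal(exs$data[y, a, x], lf$data[want[a, 1], want[a, 2], y, x])
  # serpentine y-t: v fastest, alternating per u column; layout (W, A, H)
  eyt <- lf_to_epi_stack(lf, "y-t")
  wanty <- rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1))
  expect_equal(unname(eyt$traversal), unname(wanty))
  for (a in 1:4) for (y in 1:2) for (x in 1:2)
    expect_equal(eyt$data[x, a, y], lf$data[wanty[a, 1], wanty[a, 2], y, x])
})

test_that("EPI conversion is a bijection for 81 and 16 views under both schemes", {
  for (shp in list(c(9L, 9L), c(16L, 1L))) {
    lf <- lightfield(array(runif(prod(shp) * 5 * 7), c(shp, 5L, 7L)))
    for (o in c("x-s", "y-t")) for (sc in c("serpentine", "raster")) {
      epi <- lf_to_epi_stack(lf, o, sc)
      back <- epi_stack_to_lf(epi)
      expect_identical(back$data, lf$data)
    }
  }
})

test_that("corrupted traversal metadata is rejected", {
  lf <- coded_lightfield(3L, 3L, 4L, 4L)
  epi <- lf_to_epi_stack(lf, "x-s")
  epi$traversal[2, ] <- epi$traversal[1, ]
  expect_error(epi_stack_to_lf(epi), "traversal")
})

test_that("patch grids cover every pixel and stitching is exact", {
  # origin arithmetic at a realistic full-frame size
  o <- ns$patch_origins(459L, 128L, 16L)
  covered <- rep(FALSE, 459)
  for (s in o) covered[s:(s + 127L)] <- TRUE
  expect_true(all(covered))
  # round trip on a real array
  lf <- lightfield(array(runif(4 * 1 * 100 * 90), c(4, 1, 100, 90)))
  ex <- extract_patches(lf, 32L, 8L)
  expect_true(all(ns$stitch_weight_map(ex$grid) == 1))
  st <- stitch_patches(ex$patches, ex$grid, lf)
  expect_equal(st$data, lf$data, tolerance = 1e-12)
  # single patch for an exact-size input
  lf1 <- lightfield(array(runif(4 * 1 * 32 * 32), c(4, 1, 32, 32)))
  ex1 <- extract_patches(lf1, 32L, 8L)
  expect_equal(length(ex1$patches), 1L)
  expect_equal(unname(unlist(ex1$grid$origins[1, ])), c(1L, 1L))
  # smaller-than-patch input is reflection-padded then cropped back
  lfs <- lightfield(array(runif(4 * 1 * 20 * 24), c(4, 1, 20, 24)))
  exs <- extract_patches(lfs, 32L, 8L)
  sts <- stitch_patches(exs$patches, exs$grid, lfs)
  expect_equal(sts$data, lfs$data, tolerance = 1e-12)
  # identical-valued overlapping patches blend to a constant
  lfc <- lightfield(array(3, c(2, 1, 50, 50)))
  exc <- extract_patches(lfc, 32L, 8L)
  stc <- stitch_patches(exc$patches, exc$grid, lfc)
  expect_true(all(abs(stc$data - 3) < 1e-12))
  expect_error(stitch_patches(exc$patches[-1], exc$grid, lfc), "expected")
})

test_that("central-view selection commutes with patch extraction", {
  lf <- lightfield(array(runif(5 * 5 * 40 * 40), c(5, 5, 40, 40)))
  a <- extract_patches(select_central_views(lf, 3L), 16L, 4L)
  b <- extract_patches(lf, 16L, 4L)
  for (i in seq_along(a$patches))
    expect_identical(a$patches[[i]], b$patches[[i]][2:4, 2:4, , , drop = FALSE])
})
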