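# The reverse-mode engine is validated against central finite differences
# on small random tensors; every layer the network uses is covered.

ns <- asNamespace("lfdenoise")

test_that("convolution, pooling and upsampling gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(2 * 3 * 4 * 5), c(2, 3, 4, 5))
  cv <- ns$init_conv3(2L, 3L, 3L)
  xn <- ns$ad_param(x)
  loss <- ns$ad_mean_sq(ns$ad_conv3(xn, cv$w, cv$b, 3L),
                        ns$ad_const(array(0, c(3, 3, 4, 5))))
  ns$ad_backward(loss)
  f <- function(v) mean(ad_value(ns$ad_conv3(ns$ad_const(v), ns$ad_const(cv$w$v),
                                             ns$ad_const(cv$b$v), 3L))^2)
  expect_lt(max(abs(num_grad(f, x) - xn$grad)), 1e-7)
  fw <- function(wv) mean(ad_value(ns$ad_conv3(ns$ad_const(x),
                                               ns$ad_const(array(wv, dim(cv$w$v))),
                                               ns$ad_const(cv$b$v), 3L))^2)
  expect_lt(max(abs(num_grad(fw, cv$w$v) - cv$w$grad)), 1e-7)

  x2 <- array(rnorm(3 * 6 * 5), c(3, 6, 5))
  cv2 <- ns$init_conv2(3L, 2L, 3L)
  xn2 <- ns$ad_param(x2)
  loss2 <- ns$ad_mean_sq(ns$ad_conv2(xn2, cv2$w, cv2$b, 3L),
                         ns$ad_const(array(0, c(2, 6, 5))))
  ns$ad_backward(loss2)
  f2 <- function(v) mean(ad_value(ns$ad_conv2(ns$ad_const(v), ns$ad_const(cv2$w$v),
                                              ns$ad_const(cv2$b$v), 3L))^2)
  expect_lt(max(abs(num_grad(f2, x2) - xn2$grad)), 1e-7)

  xp <- array(rnorm(2 * 5 * 6 * 7), c(2, 5, 6, 7))
  xn3 <- ns$ad_param(xp)
  l3 <- ns$ad_mean_sq(ns$ad_maxpool3(xn3), ns$ad_const(array(0, c(2, 3, 3, 4))))
  ns$ad_backward(l3)
  f3 <- function(v) mean(ad_value(ns$ad_maxpool3(ns$ad_const(v)))^2)
  expect_lt(max(abs(num_grad(f3, xp) - xn3$grad)), 1e-7)

  xu <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  xn4 <- ns$ad_param(xu)
  l4 <- ns$ad_mean_sq(ns$ad_upsample3(xn4, c(5L, 6L, 7L)),
                      ns$ad_const(array(0, c(2, 5, 6, 7))))
  ns$ad_backward(l4)
  f4 <- function(v) mean(ad_value(ns$ad_upsample3(ns$ad_const(v), c(5L, 6L, 7L)))^2)
  expect_lt(max(abs(num_grad(f4, xu) - xn4$grad)), 1e-7)
})

test_that("attention and layer normalization gradients match finite differences", {
  set.seed(12)
  Dm <- 8L; S <- 5L; B <- 2L
  q <- matrix(rnorm(Dm * S * B), Dm)
  k <- matrix(rnorm(Dm * S * B), Dm)
  v <- matrix(rnorm(Dm * S * B), Dm)
  qn <- ns$ad_param(q); kn <- ns$ad_param(k); vn <- ns$ad_param(v)
  loss <- ns$ad_mean_sq(ns$ad_attention(qn, kn, vn, S, B, 2L),
                        ns$ad_const(matrix(0, Dm, S * B)))
  ns$ad_backward(loss)
  fa <- function(m, which) {
    args <- list(q, k, v); args[[which]] <- m
    mean(ad_value(ns$ad_attention(ns$ad_const(args[[1]]), ns$ad_const(args[[2]]),
                                  ns$ad_const(args[[3]]), S, B, 2L))^2)
  }
  expect_lt(max(abs(num_grad(function(m) fa(m, 1), q) - qn$grad)), 1e-7)
  expect_lt(max(abs(num_grad(function(m) fa(m, 2), k) - kn$grad)), 1e-7)
  expect_lt(max(abs(num_grad(function(m) fa(m, 3), v) - vn$grad)), 1e-7)

  xl <- matrix(rnorm(6 * 4), 6)
  g <- ns$ad_param(runif(6, 0.5, 1.5)); b <- ns$ad_param(rnorm(6))
  xn <- ns$ad_param(xl)
  loss <- ns$ad_mean_sq(ns$ad_layernorm(xn, g, b), ns$ad_const(matrix(0, 6, 4)))
  ns$ad_backward(loss)
  fl <- function(v) mean(ad_value(ns$ad_layernorm(ns$ad_const(v), ns$ad_const(g$v),
                                                  ns$ad_const(b$v)))^2)
  expect_lt(max(abs(num_grad(fl, xl) - xn$grad)), 1e-6)
})

test_that("pooling/broadcast ops used by the attention modules differentiate correctly", {
  set.seed(13)
  x <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  for (op in list(ns$ad_mean_spatial, ns$ad_max_spatial)) {
    xn <- ns$ad_param(x)
    y <- op(xn)
    l <- ns$ad_mean_sq(y, ns$ad_const(numeric(4)))
    ns$ad_backward(l)
    f <- function(v) mean(ad_value(op(ns$ad_const(v)))^2)
    expect_lt(max(abs(num_grad(f, x) - xn$grad)), 1e-7)
  }
  for (op in list(ns$ad_mean_channels, ns$ad_max_channels)) {
    xn <- ns$ad_param(x)
    l <- ns$ad_mean_sq(op(xn), ns$ad_const(array(0, c(5, 6))))
    ns$ad_backward(l)
    f <- function(v) mean(ad_value(op(ns$ad_const(v)))^2)
    expect_lt(max(abs(num_grad(f, x) - xn$grad)), 1e-7)
  }
  s <- rnorm(4)
  xn <- ns$ad_param(x); sn <- ns$ad_param(s)
  l <- ns$ad_mean_sq(ns$ad_mul_channel(xn, sn), ns$ad_const(array(0, dim(x))))
  ns$ad_backward(l)
  fs <- function(v) mean(ad_value(ns$ad_mul_channel(ns$ad_const(x), ns$ad_const(v)))^2)
  expect_lt(max(abs(num_grad(fs, s) - sn$grad)), 1e-7)
  m <- matrix(rnorm(5 * 6), 5)
  xn <- ns$ad_param(x); mn <- ns$ad_param(m)
  l <- ns$ad_mean_sq(ns$ad_mul_spatial(xn, mn), ns$ad_const(array(0, dim(x))))
  ns$ad_backward(l)
  fm <- function(v) mean(ad_value(ns$ad_mul_spatial(ns$ad_const(x), ns$ad_const(v)))^2)
  expect_lt(max(abs(num_grad(fm, m) - mn$grad)), 1e-7)
})

test_that("no-grad evaluation builds no graph and constants fold", {
  x <- ns$ad_const(matrix(1:4, 2))
  y <- ns$ad_add(x, x)
  expect_true(y$is_leaf)              # const + const folds to a const
  p <- ns$ad_param(matrix(1:4, 2))
  z <- ns$ad_no_grad(ns$ad_add(p, p))
  expect_true(z$is_leaf)              # no graph recorded under no_grad
  z2 <- ns$ad_add(p, p)
  expect_false(z2$is_leaf)
})

test_that("gradients accumulate across reuse of the same node", {
  p <- ns$ad_param(2)
  y <- ns$ad_add(ns$ad_scale(p, 3), ns$ad_scale(p, 4))   # 7p
  ns$ad_backward(y)
  expect_equal(as.numeric(p$grad), 7)
})
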