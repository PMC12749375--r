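#' @useDynLib lfdenoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation over R arrays.
#
# A node is an environment holding: v (value, an array/matrix/scalar with
# dim attributes), grad (accumulated cotangent), parents (list of nodes),
# bw (vector-Jacobian product: function(grad) -> list of parent grads),
# req (TRUE if any ancestor is a parameter), is_leaf.
#
# Ops called on nodes whose ancestors contain no parameter collapse to
# constants: inference builds no graph and stores no activations.
# ------------------------------------------------------------------------

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_node <- function(v, parents = list(), bw = NULL, req = FALSE, leaf = FALSE) {
  n <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  n$id <- .ad$counter
  n$v <- v
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  n$req <- req
  n$is_leaf <- leaf
  class(n) <- "ad_node"
  n
}

#' @export
print.ad_node <- function(x, ...) {
  cat("<ad_node", if (x$is_leaf) "param" else "op",
      paste(dim(x$v) %||% length(x$v), collapse = "x"), ">\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ad_const <- function(v) ad_node(v, leaf = TRUE, req = FALSE)

ad_param <- function(v) ad_node(v, leaf = TRUE, req = TRUE)

#' Extract the value array from an autodiff node
#'
#' The package's network forwards return lightweight graph nodes;
#' `ad_value()` unwraps the plain numeric array.
#'
#' @param x an `ad_node` (or any object, returned unchanged).
#' @return The underlying numeric array.
#' @export
ad_value <- function(x) if (inherits(x, "ad_node")) x$v else x

# Build an op node; constant-fold when no parent requires gradients or
# when evaluating under ad_no_grad() (inference: no graph, no activations).
ad_op <- function(v, parents, bw) {
  if (isTRUE(.ad$no_grad)) return(ad_const(v))
  req <- any(vapply(parents, function(p) p$req, logical(1)))
  if (!req) return(ad_const(v))
  ad_node(v, parents = parents, bw = bw, req = TRUE)
}

# Evaluate `expr` without recording the graph (forward values only).
ad_no_grad <- function(expr) {
  old <- isTRUE(.ad$no_grad)
  .ad$no_grad <- TRUE
  on.exit(.ad$no_grad <- old)
  expr
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Reverse pass from a scalar root. Accumulates gradients into every
# parameter leaf reachable from `root`.
ad_backward <- function(root) {
  stopifnot(length(root$v) == 1L)
  if (!root$req) return(invisible(NULL))
  order <- vector("list", 256L)
  no <- 0L
  state <- new.env(hash = TRUE, parent = emptyenv())
  stack <- vector("list", 64L)
  ns <- 1L
  stack[[1L]] <- root
  while (ns > 0L) {
    n <- stack[[ns]]
    key <- as.character(n$id)
    st <- get0(key, envir = state, inherits = FALSE)
    if (is.null(st)) {
      assign(key, 0L, envir = state)
      for (p in n$parents) {
        if (p$req && is.null(get0(as.character(p$id), envir = state, inherits = FALSE))) {
          ns <- ns + 1L
          if (ns > length(stack)) stack <- c(stack, vector("list", length(stack)))
          stack[[ns]] <- p
        }
      }
    } else if (st == 0L) {
      assign(key, 1L, envir = state)
      no <- no + 1L
      if (no > length(order)) order <- c(order, vector("list", length(order)))
      order[[no]] <- n
      ns <- ns - 1L
    } else {
      ns <- ns - 1L
    }
  }
  root$grad <- 1
  for (i in seq.int(no, 1L)) {
    n <- order[[i]]
    if (is.null(n$bw) || is.null(n$grad)) next
    gs <- n$bw(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$req || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!n$is_leaf) n$grad <- NULL
  }
  invisible(NULL)
}

# ---- elementwise and linear-algebra ops ---------------------------------

ad_add <- function(a, b) ad_op(a$v + b$v, list(a, b), function(g) list(g, g))

ad_sub <- function(a, b) ad_op(a$v - b$v, list(a, b), function(g) list(g, -g))

ad_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) ad_op(a$v * s, list(a), function(g) list(g * s))

ad_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), t(av) %*% g))
}

# y = W x + b with b recycled across columns of x.
ad_lin <- function(W, x, b) {
  Wv <- W$v; xv <- x$v
  v <- Wv %*% xv + b$v
  ad_op(v, list(W, x, b),
        function(g) list(g %*% t(xv), t(Wv) %*% g, rowSums(g)))
}

ad_lrelu <- function(a, slope = 0.1) {
  av <- a$v
  m <- slope + (1 - slope) * (av > 0)
  v <- av * m
  ad_op(v, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ad_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_gelu <- function(a) {
  av <- a$v
  ph <- stats::pnorm(av)
  ad_op(av * ph, list(a),
        function(g) list(g * (ph + av * stats::dnorm(av))))
}

ad_detach <- function(a) ad_const(a$v)

# ---- shape ops ----------------------------------------------------------

ad_reshape <- function(a, d) {
  od <- dim(a$v) %||% length(a$v)
  v <- a$v
  dim(v) <- d
  ad_op(v, list(a), function(g) { dim(g) <- od; list(g) })
}

ad_permute <- function(a, perm) {
  v <- aperm(a$v, perm)
  inv <- order(perm)
  ad_op(v, list(a), function(g) list(aperm(g, inv)))
}

# Keep an index subset along every axis of an array (idx: list of index
# vectors, one per axis); backward scatters into zeros.
ad_index <- function(a, idx) {
  od <- dim(a$v)
  stopifnot(length(idx) == length(od))
  v <- do.call(`[`, c(list(a$v), idx, list(drop = FALSE)))
  ad_op(v, list(a), function(g) {
    gx <- array(0, od)
    gx <- do.call(`[<-`, c(list(gx), idx, list(value = g)))
    list(gx)
  })
}

ad_cat <- function(a, b, axis = 1L) {
  da <- dim(a$v); db <- dim(b$v)
  v <- .cat_arrays(a$v, b$v, axis)
  na <- da[axis]
  nd <- length(da)
  ad_op(v, list(a, b), function(g) {
    ia <- rep(list(quote(expr = )), nd)
    ib <- ia
    ia[[axis]] <- seq_len(na)
    ib[[axis]] <- na + seq_len(db[axis])
    list(do.call(`[`, c(list(g), ia, list(drop = FALSE))),
         do.call(`[`, c(list(g), ib, list(drop = FALSE))))
  })
}

.cat_arrays <- function(a, b, axis) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  perm <- c(setdiff(seq_len(nd), axis), axis)
  ap <- aperm(a, perm); bp <- aperm(b, perm)
  keep <- da[perm[-nd]]
  m <- c(ap, bp)
  dim(m) <- c(keep, da[axis] + db[axis])
  aperm(m, order(perm))
}

# ---- convolution, pooling, upsampling -----------------------------------

# Convolutions are lowered to im2col + BLAS matrix products; the column
# matrix is kept in the node closure so the backward pass reuses it (the
# dominant cost on a memory-bound machine is building it).
ad_conv3 <- function(x, w, b, k, pad = (k - 1L) %/% 2L) {
  dx <- dim(x$v)   # (C, D, H, W)
  dw <- dim(w$v)   # (Co, Ci, k, k, k)
  stopifnot(dx[1] == dw[2])
  Co <- dw[1]; R <- dx[1] * k^3
  W2 <- matrix(w$v, Co, R)
  cols <- .im2col3(x$v, dx[1], dx[2], dx[3], dx[4], k, pad)
  v <- W2 %*% cols + b$v
  dim(v) <- c(Co, dx[2], dx[3], dx[4])
  ad_op(v, list(x, w, b), function(g) {
    gym <- matrix(g, Co)
    gw <- tcrossprod(gym, cols)
    dim(gw) <- dw
    gx <- .col2im3(crossprod(W2, gym), dx[1], dx[2], dx[3], dx[4], k, pad)
    dim(gx) <- dx
    list(gx, gw, rowSums(gym))
  })
}

ad_conv2 <- function(x, w, b, k, pad = (k - 1L) %/% 2L) {
  dx <- dim(x$v)   # (C, H, W)
  dw <- dim(w$v)   # (Co, Ci, k, k)
  stopifnot(dx[1] == dw[2])
  Co <- dw[1]; R <- dx[1] * k^2
  W2 <- matrix(w$v, Co, R)
  cols <- .im2col2(x$v, dx[1], dx[2], dx[3], k, pad)
  v <- W2 %*% cols + b$v
  dim(v) <- c(Co, dx[2], dx[3])
  ad_op(v, list(x, w, b), function(g) {
    gym <- matrix(g, Co)
    gw <- tcrossprod(gym, cols)
    dim(gw) <- dw
    gx <- .col2im2(crossprod(W2, gym), dx[1], dx[2], dx[3], k, pad)
    dim(gx) <- dx
    list(gx, gw, rowSums(gym))
  })
}

ad_maxpool3 <- function(x) {
  dx <- dim(x$v)
  r <- .maxpool3_fwd(x$v, dx[1], dx[2], dx[3], dx[4])
  v <- r$y
  dim(v) <- r$dim
  idx <- r$idx
  n_in <- length(x$v)
  ad_op(v, list(x), function(g) {
    gx <- .maxpool3_bwd(g, idx, n_in)
    dim(gx) <- dx
    list(gx)
  })
}

# Nearest-neighbour 2x upsampling of the three trailing axes of (C,D,H,W),
# cropped to `odim` (the pre-pooling size, which may be odd).
ad_upsample3 <- function(x, odim) {
  dx <- dim(x$v)
  id <- rep(seq_len(dx[2]), each = 2L)[seq_len(odim[1])]
  ih <- rep(seq_len(dx[3]), each = 2L)[seq_len(odim[2])]
  iw <- rep(seq_len(dx[4]), each = 2L)[seq_len(odim[3])]
  v <- x$v[, id, ih, iw, drop = FALSE]
  ad_op(v, list(x), function(g) {
    g <- .pair_sum_axis(g, 2L, dx[2])
    g <- .pair_sum_axis(g, 3L, dx[3])
    g <- .pair_sum_axis(g, 4L, dx[4])
    list(g)
  })
}

# Sum output positions mapping to the same input position under 2x nearest
# upsampling along `axis` (adjoint of index replication).
.pair_sum_axis <- function(g, axis, n_in) {
  d <- dim(g)
  n_out <- d[axis]
  idx1 <- seq(1L, n_out, by = 2L)
  idx2 <- seq(2L, n_out, by = 2L)
  pick <- function(i) {
    ia <- rep(list(quote(expr = )), length(d))
    ia[[axis]] <- i
    do.call(`[`, c(list(g), ia, list(drop = FALSE)))
  }
  a <- pick(idx1)
  if (length(idx2)) {
    b <- pick(idx2)
    if (length(idx2) < length(idx1)) {
      ia <- rep(list(quote(expr = )), length(d))
      ia[[axis]] <- seq_along(idx2)
      a <- do.call(`[<-`, c(list(a), ia, list(value =
        do.call(`[`, c(list(a), ia, list(drop = FALSE))) + b)))
    } else a <- a + b
  }
  out <- a
  dm <- d; dm[axis] <- n_in
  stopifnot(all(dim(out) == dm))
  out
}

# ---- normalization and attention ----------------------------------------

# Layer normalization over the rows (feature axis) of a (D, N) matrix,
# independently per column, with learned gain and bias of length D.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$v
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  va <- colMeans(xc * xc)
  sd <- sqrt(va + eps)
  xh <- sweep(xc, 2L, sd, "/")
  gv <- gamma$v
  v <- xh * gv + beta$v
  D <- nrow(xv)
  ad_op(v, list(x, gamma, beta), function(g) {
    dxh <- g * gv
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xh)
    gx <- sweep(dxh, 2L, m1) - xh * rep(m2, each = D)
    gx <- sweep(gx, 2L, sd, "/")
    list(gx, rowSums(g * xh), rowSums(g))
  })
}

# Fused multi-head scaled-dot-product attention. q, k, v are (Dm, S*B)
# matrices of projected tokens; columns are grouped by batch element
# (sequence position fastest). Returns (Dm, S*B).
ad_attention <- function(q, k, v, S, B, heads) {
  Dm <- nrow(q$v)
  stopifnot(Dm %% heads == 0L, ncol(q$v) == S * B)
  Dh <- Dm %/% heads
  qv <- q$v; kv <- k$v; vv <- v$v
  out <- matrix(0, Dm, S * B)
  Ps <- vector("list", B * heads)
  sc <- 1 / sqrt(Dh)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * S + seq_len(S)
    for (h in seq_len(heads)) {
      rows <- (h - 1L) * Dh + seq_len(Dh)
      Qh <- qv[rows, cols, drop = FALSE]
      Kh <- kv[rows, cols, drop = FALSE]
      Vh <- vv[rows, cols, drop = FALSE]
      sco <- crossprod(Qh, Kh) * sc           # (S, S) rows = queries
      sco <- sco - apply(sco, 1L, max)
      P <- exp(sco)
      P <- P / rowSums(P)
      out[rows, cols] <- Vh %*% t(P)
      Ps[[(b - 1L) * heads + h]] <- P
    }
  }
  ad_op(out, list(q, k, v), function(g) {
    gq <- matrix(0, Dm, S * B); gk <- gq; gv_ <- gq
    for (b in seq_len(B)) {
      cols <- (b - 1L) * S + seq_len(S)
      for (h in seq_len(heads)) {
        rows <- (h - 1L) * Dh + seq_len(Dh)
        P <- Ps[[(b - 1L) * heads + h]]
        Qh <- qv[rows, cols, drop = FALSE]
        Kh <- kv[rows, cols, drop = FALSE]
        Vh <- vv[rows, cols, drop = FALSE]
        gO <- g[rows, cols, drop = FALSE]
        gv_[rows, cols] <- gO %*% P
        gP <- crossprod(gO, Vh)               # (S, S)
        gS <- (gP - rowSums(gP * P)) * P * sc
        gq[rows, cols] <- Kh %*% t(gS)
        gk[rows, cols] <- Qh %*% gS
      }
    }
    list(gq, gk, gv_)
  })
}

# ---- reductions, broadcasting, losses -----------------------------------

ad_mean_abs <- function(a, b) {
  d <- a$v - b$v
  n <- length(d)
  ad_op(mean(abs(d)), list(a, b), function(g) {
    s <- g * sign(d) / n
    list(s, -s)
  })
}

ad_mean_sq <- function(a, b) {
  d <- a$v - b$v
  n <- length(d)
  ad_op(mean(d * d), list(a, b), function(g) {
    s <- g * 2 * d / n
    list(s, -s)
  })
}

# Channel-wise global pooling over all non-channel axes of (C, ...).
ad_mean_spatial <- function(x) {
  d <- dim(x$v)
  m <- matrix(x$v, d[1])
  npix <- ncol(m)
  ad_op(rowMeans(m), list(x), function(g) {
    gx <- matrix(rep(g / npix, npix), d[1])
    dim(gx) <- d
    list(gx)
  })
}

ad_max_spatial <- function(x) {
  d <- dim(x$v)
  m <- matrix(x$v, d[1])
  j <- max.col(m, ties.method = "first")
  v <- m[cbind(seq_len(d[1]), j)]
  ad_op(v, list(x), function(g) {
    gx <- matrix(0, d[1], ncol(m))
    gx[cbind(seq_len(d[1]), j)] <- g
    dim(gx) <- d
    list(gx)
  })
}

# Per-pixel pooling over the channel axis of (C, H, W) -> (H, W).
ad_mean_channels <- function(x) {
  d <- dim(x$v)
  m <- matrix(x$v, d[1])
  v <- colMeans(m)
  dim(v) <- d[-1]
  ad_op(v, list(x), function(g) {
    gx <- matrix(rep(as.vector(g) / d[1], each = d[1]), d[1])
    dim(gx) <- d
    list(gx)
  })
}

ad_max_channels <- function(x) {
  d <- dim(x$v)
  m <- matrix(x$v, d[1])
  i <- apply(m, 2L, which.max)
  v <- m[cbind(i, seq_len(ncol(m)))]
  dim(v) <- d[-1]
  ad_op(v, list(x), function(g) {
    gx <- matrix(0, d[1], ncol(m))
    gx[cbind(i, seq_len(ncol(m)))] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# x (C, ...) scaled per channel by s (C).
ad_mul_channel <- function(x, s) {
  d <- dim(x$v)
  sv <- as.vector(s$v)
  xv <- x$v
  v <- xv * sv            # channel axis is fastest: recycling aligns
  ad_op(v, list(x, s), function(g) {
    gs <- rowSums(matrix(g * xv, d[1]))
    list(g * sv, gs)
  })
}

# x (C, H, W) scaled per pixel by m (H, W).
ad_mul_spatial <- function(x, m) {
  d <- dim(x$v)
  mv <- rep(as.vector(m$v), each = d[1])
  xv <- x$v
  ad_op(xv * mv, list(x, m), function(g) {
    gm <- colSums(matrix(g * xv, d[1]))
    dim(gm) <- d[-1]
    list(g * mv, gm)
  })
}
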