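# ------------------------------------------------------------------------
# Losses, optimization schedule, and the self-supervised training loop.
# ------------------------------------------------------------------------

#' Loss weights
#'
#' Defaults of the composite objective: the pair loss
#' mixes mean absolute error and mean squared error with equal weights 0.5;
#' the fusion loss weighs the sub-network-consistency half with 0.4 and the
#' masked-target half with 0.6, each half averaging its two terms (0.5/0.5).
#'
#' @param l1,l2 pair-loss weights for the MAE and MSE terms.
#' @param fusion_subnet,fusion_mask outer fusion-loss weights.
#' @param inner inner averaging weight for each fusion half.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(l1 = 0.5, l2 = 0.5, fusion_subnet = 0.4,
                         fusion_mask = 0.6, inner = 0.5) {
  stopifnot(l1 >= 0, l2 >= 0, fusion_subnet >= 0, fusion_mask >= 0, inner >= 0)
  structure(list(l1 = l1, l2 = l2, fusion_subnet = fusion_subnet,
                 fusion_mask = fusion_mask, inner = inner),
            class = "loss_weights")
}

#' Pair loss: equally weighted L1 + L2
#'
#' `0.5 * mean(|X - Y|) + 0.5 * mean((X - Y)^2)` -- pixel-wise mean absolute
#' error plus pixel-wise mean square error. Accepts plain arrays (returns a
#' number) or `ad_node`s (returns a differentiable node).
#'
#' @param x,y same-shape arrays or `ad_node`s.
#' @param w a [loss_weights()].
#' @return Scalar (or scalar `ad_node`).
#' @export
pair_loss <- function(x, y, w = loss_weights()) {
  if (inherits(x, "ad_node") || inherits(y, "ad_node")) {
    if (!inherits(x, "ad_node")) x <- ad_const(x)
    if (!inherits(y, "ad_node")) y <- ad_const(y)
    if (!all((dim(x$v) %||% length(x$v)) == (dim(y$v) %||% length(y$v))))
      stop("pair_loss inputs must share one shape")
    return(ad_add(ad_scale(ad_mean_abs(x, y), w$l1),
                  ad_scale(ad_mean_sq(x, y), w$l2)))
  }
  if (length(x) != length(y)) stop("pair_loss inputs must share one shape")
  d <- x - y
  w$l1 * mean(abs(d)) + w$l2 * mean(d * d)
}

#' Fusion loss with truncated gradients
#'
#' `0.4 * [0.5 * loss(Y1, Yf) + 0.5 * loss(Y2, Yf)] +
#'  0.6 * [0.5 * loss(Ym1, Yf) + 0.5 * loss(Ym2, Yf)]`
#' where `loss` is [pair_loss()]. When given `ad_node`s, `y1` and `y2` enter
#' with their gradients severed (the fusion objective trains only the fusion
#' module; the sub-networks learn from their own pair losses).
#'
#' @param y1,y2 sub-network outputs rearranged to `(A, h, w)`.
#' @param yf fusion output, same shape.
#' @param ym1,ym2 mask-downsampled raw-patch targets, same shape.
#' @param w a [loss_weights()].
#' @return Scalar (or scalar `ad_node`).
#' @export
fusion_loss <- function(y1, y2, yf, ym1, ym2, w = loss_weights()) {
  nodes <- inherits(yf, "ad_node")
  if (nodes) {
    if (inherits(y1, "ad_node")) y1 <- ad_detach(y1)
    if (inherits(y2, "ad_node")) y2 <- ad_detach(y2)
    sub <- ad_add(ad_scale(pair_loss(y1, yf, w), w$inner),
                  ad_scale(pair_loss(y2, yf, w), w$inner))
    msk <- ad_add(ad_scale(pair_loss(ym1, yf, w), w$inner),
                  ad_scale(pair_loss(ym2, yf, w), w$inner))
    return(ad_add(ad_scale(sub, w$fusion_subnet), ad_scale(msk, w$fusion_mask)))
  }
  w$fusion_subnet * (w$inner * pair_loss(y1, yf, w) + w$inner * pair_loss(y2, yf, w)) +
    w$fusion_mask * (w$inner * pair_loss(ym1, yf, w) + w$inner * pair_loss(ym2, yf, w))
}

#' Total training objective
#'
#' Plain sum of the two sub-network pair losses and the fusion loss.
#'
#' @param loss_xs,loss_yt,loss_fusion finite scalars (or nodes).
#' @return Scalar (or scalar `ad_node`).
#' @export
total_loss <- function(loss_xs, loss_yt, loss_fusion) {
  if (inherits(loss_xs, "ad_node"))
    return(ad_add(ad_add(loss_xs, loss_yt), loss_fusion))
  vals <- c(loss_xs, loss_yt, loss_fusion)
  if (any(!is.finite(vals))) stop("total_loss requires finite inputs")
  sum(vals)
}

#' Optimization schedule
#'
#' Adam with `beta1 = 0.9`, `beta2 = 0.999`; the learning rate starts at
#' `1e-4` and decays by a factor 0.3 every 5 epochs:
#' `lr(e) = 1e-4 * 0.3^floor(e / 5)`. Training typically converges within
#' 20-25 epochs; the default is 25.
#'
#' @param lr0 initial learning rate.
#' @param decay multiplicative decay factor.
#' @param decay_every epochs between decays.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param epochs default epoch count.
#' @param seed RNG seed for the training loop.
#' @return An object of class `optim_spec`.
#' @export
optim_spec <- function(lr0 = 1e-4, decay = 0.3, decay_every = 5L,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       epochs = 25L, seed = 1L) {
  structure(list(lr0 = lr0, decay = decay, decay_every = decay_every,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 epochs = epochs, seed = seed), class = "optim_spec")
}

#' @rdname optim_spec
#' @param epoch 0-based epoch index.
#' @param spec an `optim_spec`.
#' @return `lr_at`: the learning rate at that epoch.
#' @export
lr_at <- function(epoch, spec = optim_spec()) {
  stopifnot(epoch >= 0)
  spec$lr0 * spec$decay^(epoch %/% spec$decay_every)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$v * 0)
  st$v <- lapply(params, function(p) p$v * 0)
  st$t <- 0L
  st
}

adam_step <- function(st, params, lr, spec) {
  st$t <- st$t + 1L
  b1 <- spec$beta1; b2 <- spec$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$v <- p$v - lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + spec$eps)
  }
  invisible(NULL)
}

# ---- the training step and loop -----------------------------------------

# Serialize a 4D (U, V, H, W) patch to (A, H, W) in the x-s traversal order
# (the canonical angular ordering of fusion outputs and mask targets).
serialize_patch_angular <- function(patch, scheme = "serpentine") {
  d <- dim(patch)
  trav <- angular_traversal(d[1], d[2], "x-s", scheme)
  flat <- trav[, 1] + d[1] * (trav[, 2] - 1L)
  x <- patch
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  x[flat, , , drop = FALSE]
}

# Permutation mapping the y-t angular serialization onto the x-s one.
yt_to_xs_angular_perm <- function(U, V, scheme = "serpentine") {
  txs <- angular_traversal(U, V, "x-s", scheme)
  tyt <- angular_traversal(U, V, "y-t", scheme)
  fxs <- txs[, 1] + U * (txs[, 2] - 1L)
  fyt <- tyt[, 1] + U * (tyt[, 2] - 1L)
  match(fxs, fyt)
}

# One self-supervised step on a 4D patch. Returns the three loss values.
lf_train_step <- function(models, patch, parity, weights, scheme,
                          adam_xs, adam_yt, adam_fus, lr, spec,
                          update = TRUE) {
  d <- dim(patch)
  U <- d[1]; V <- d[2]; ps <- d[3]
  A <- U * V
  lfp <- lightfield(patch, bit_depth = 16L)
  epi_xs <- lf_to_epi_stack(lfp, "x-s", scheme)
  epi_yt <- lf_to_epi_stack(lfp, "y-t", scheme)
  pr_xs <- split_substack_pair(epi_xs$data, parity)
  pr_yt <- split_substack_pair(epi_yt$data, parity)

  out_xs <- forward_subnetwork(models$xs, ad_const(pr_xs$input))
  out_yt <- forward_subnetwork(models$yt, ad_const(pr_yt$input))
  l_xs <- pair_loss(ad_const(pr_xs$target), out_xs, weights)
  l_yt <- pair_loss(ad_const(pr_yt$target), out_yt, weights)

  # rearrange the parity-matched halves to (A, h, w) on the common subgrid
  inner_idx <- seq(parity + 1L, ps, by = 2L)
  h2 <- ps %/% 2L
  y1 <- ad_permute(out_xs, c(2L, 1L, 3L))          # (A, rows, x)
  y1 <- ad_index(y1, list(seq_len(A), seq_len(h2), inner_idx))
  y2 <- ad_permute(out_yt, c(2L, 3L, 1L))          # (A_yt, y, cols)
  y2 <- ad_index(y2, list(seq_len(A), inner_idx, seq_len(h2)))
  pa <- yt_to_xs_angular_perm(U, V, scheme)
  y2 <- ad_index(y2, list(pa, seq_len(h2), seq_len(h2)))

  y1d <- ad_detach(y1); y2d <- ad_detach(y2)
  z <- interleave_fusion_input(y1d, y2d)
  yf <- forward_fusion(models$fusion, z)

  par_as <- serialize_patch_angular(patch, scheme)
  mp <- sample_mask_pair(c(ps, ps))
  ym1 <- apply_mask(par_as, mp$m1)
  ym2 <- apply_mask(par_as, mp$m2)
  l_fus <- fusion_loss(y1d, y2d, yf, ad_const(ym1), ad_const(ym2), weights)

  tot <- total_loss(l_xs, l_yt, l_fus)
  if (!is.finite(tot$v)) stop("non-finite training loss")
  if (update) {
    ad_backward(tot)
    adam_step(adam_xs$st, adam_xs$params, lr, spec)
    adam_step(adam_yt$st, adam_yt$params, lr, spec)
    adam_step(adam_fus$st, adam_fus$params, lr, spec)
    ad_zero_grad(adam_xs$params)
    ad_zero_grad(adam_yt$params)
    ad_zero_grad(adam_fus$params)
  }
  c(loss_xs = l_xs$v, loss_yt = l_yt$v, loss_fusion = l_fus$v, total = tot$v)
}

#' Train the denoising model set
#'
#' Iterates over the training set: each step runs both sub-networks on the
#' parity-split EPI sub-stacks of one patch (pair losses), feeds their
#' gradient-severed, parity-matched outputs through the fusion module
#' together with freshly drawn orthogonal mask targets (fusion loss), sums
#' the three losses, back-propagates and applies one Adam update per module.
#' Fully deterministic given the optimizer seed.
#'
#' @param models from [build_lf_models()]; updated in place and returned.
#' @param tset an `lf_training_set`.
#' @param spec an [optim_spec()].
#' @param weights a [loss_weights()].
#' @param epochs passes over the training set (default `spec$epochs`);
#'   0 returns the models untouched.
#' @param max_steps optional cap on total update steps across epochs.
#' @param verbose print a line per epoch.
#' @return `list(models, history, epochs)` -- `history` is a per-step
#'   data.frame of the three losses and their total.
#' @export
train_lf_denoiser <- function(models, tset, spec = optim_spec(),
                              weights = loss_weights(), epochs = NULL,
                              max_steps = Inf, verbose = FALSE) {
  stopifnot(inherits(tset, "lf_training_set"))
  n <- nrow(tset$samples)
  if (n == 0L) stop("training set is empty")
  if (is.null(epochs)) epochs <- spec$epochs
  if (epochs == 0L || max_steps == 0L)
    return(list(models = models, history = NULL, epochs = 0L))
  set.seed(spec$seed)
  adam_xs <- list(params = model_params(models$xs), st = NULL)
  adam_yt <- list(params = model_params(models$yt), st = NULL)
  adam_fus <- list(params = model_params(models$fusion), st = NULL)
  adam_xs$st <- adam_init(adam_xs$params)
  adam_yt$st <- adam_init(adam_yt$params)
  adam_fus$st <- adam_init(adam_fus$params)
  hist <- list()
  step <- 0L
  for (e in seq_len(epochs) - 1L) {
    lr <- lr_at(e, spec)
    for (i in seq_len(n)) {
      if (step >= max_steps) break
      s <- get_training_sample(tset, i)
      losses <- lf_train_step(models, s$patch, s$parity, weights, tset$scheme,
                              adam_xs, adam_yt, adam_fus, lr, spec)
      step <- step + 1L
      hist[[step]] <- c(step = step, epoch = e, lr = lr, losses)
    }
    if (verbose) {
      ep <- do.call(rbind, hist)
      ep <- ep[ep[, "epoch"] == e, , drop = FALSE]
      message(sprintf("epoch %d: mean total loss %.6f (lr %.2g)",
                      e, mean(ep[, "total"]), lr))
    }
    if (step >= max_steps) break
  }
  history <- as.data.frame(do.call(rbind, hist))
  list(models = models, history = history, epochs = epochs)
}
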