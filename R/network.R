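# ------------------------------------------------------------------------
# The denoising architecture: two EPI sub-networks (3D U-net encoders ->
# temporal + spatial transformer stages -> decoders with a global residual
# path) and the attention-based fusion module (residual window-transformer
# route + convolution-block-attention route sharing a double convolution
# along the angular axis).
# ------------------------------------------------------------------------

#' Network configuration
#'
#' The `"standard"` preset is the full-scale design --
#' U-net encoder channels 16/32/64, a 128-channel transformer stage, eight
#' residual transformer blocks and five convolution-block-attention modules
#' in the fusion -- with the remaining transformer internals (depth 2 per
#' stage, 4 heads, window 8, MLP ratio 4, fusion embedding width 376) tuned
#' once so the total trainable parameter count lands at the 18-million
#' budget, then frozen. The `"tiny"` preset is a reduced-width configuration
#' for CPU-scale training and tests.
#'
#' @param preset `"standard"` or `"tiny"`.
#' @param angle_count flattened angular view count `A` (81 for the 9 x 9
#'   central grid, 16 for padded 13-view acquisitions). Standard network
#'   operations require `A > 8`.
#' @param ... overrides for individual fields.
#' @return An object of class `lf_network_config`.
#' @export
lf_network_config <- function(preset = c("standard", "tiny"),
                              angle_count = 81L, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "standard") list(
    preset = "standard",
    enc_channels = c(16L, 32L, 64L),
    feat_dim = 128L,
    tf_depth = 2L, tf_heads = 4L, tf_mlp_ratio = 4L,
    fusion_dim = 376L, fusion_blocks = 8L, fusion_heads = 4L,
    fusion_window = 8L, fusion_mlp_ratio = 4L,
    cbam_blocks = 5L, cbam_inner = 3L, cbam_reduction = 4L,
    route_merge = "mean",
    lrelu_slope = 0.1
  ) else list(
    preset = "tiny",
    enc_channels = c(4L, 8L, 16L),
    feat_dim = 32L,
    tf_depth = 1L, tf_heads = 4L, tf_mlp_ratio = 2L,
    fusion_dim = 32L, fusion_blocks = 2L, fusion_heads = 4L,
    fusion_window = 8L, fusion_mlp_ratio = 2L,
    cbam_blocks = 1L, cbam_inner = 1L, cbam_reduction = 4L,
    route_merge = "mean",
    lrelu_slope = 0.1
  )
  cfg$angle_count <- as.integer(angle_count)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$preset == "standard" && cfg$angle_count <= 8L)
    stop("standard preset requires more than 8 angular views")
  structure(cfg, class = "lf_network_config")
}

#' @export
print.lf_network_config <- function(x, ...) {
  cat(sprintf(
    "<lf_network_config %s: A=%d, enc %s, feat %d, fusion dim %d x %d blocks>\n",
    x$preset, x$angle_count, paste(x$enc_channels, collapse = "/"),
    x$feat_dim, x$fusion_dim, x$fusion_blocks))
  invisible(x)
}

# ---- parameter initialisation -------------------------------------------

init_conv3 <- function(Ci, Co, k, zero = FALSE) {
  w <- if (zero) array(0, c(Co, Ci, k, k, k))
  else array(stats::rnorm(Co * Ci * k^3, sd = sqrt(2 / (Ci * k^3))),
             c(Co, Ci, k, k, k))
  list(w = ad_param(w), b = ad_param(numeric(Co)), k = k)
}

init_conv2 <- function(Ci, Co, k, zero = FALSE) {
  w <- if (zero) array(0, c(Co, Ci, k, k))
  else array(stats::rnorm(Co * Ci * k^2, sd = sqrt(2 / (Ci * k^2))),
             c(Co, Ci, k, k))
  list(w = ad_param(w), b = ad_param(numeric(Co)), k = k)
}

init_lin <- function(din, dout) {
  list(W = ad_param(matrix(stats::rnorm(dout * din, sd = sqrt(1 / din)),
                           dout, din)),
       b = ad_param(numeric(dout)))
}

init_ln <- function(d) list(g = ad_param(rep(1, d)), b = ad_param(numeric(d)))

init_tf_block <- function(dim, mlp_ratio) {
  list(ln1 = init_ln(dim),
       q = init_lin(dim, dim), k = init_lin(dim, dim), v = init_lin(dim, dim),
       o = init_lin(dim, dim),
       ln2 = init_ln(dim),
       m1 = init_lin(dim, dim * mlp_ratio),
       m2 = init_lin(dim * mlp_ratio, dim))
}

# ---- sub-network ---------------------------------------------------------

#' Build one EPI sub-network
#'
#' Pipeline: three two-convolution U-net encoder stages (3D convs, leaky
#' ReLU, 2x2x2 max pooling), a 3x3x3 convolution mapping to the
#' transformer feature width, a temporal transformer attending along the
#' angular axis, a spatial transformer attending over spatial tokens, a
#' convolution back to the deepest encoder width, mirrored decoders with
#' skip connections, and a zero-initialized 1x1x1 output convolution added
#' to the input (global residual), so the freshly built network is the
#' identity map.
#'
#' @param cfg an [lf_network_config()].
#' @return An object of class `lf_subnetwork` (parameters + config).
#' @export
build_subnetwork <- function(cfg) {
  if (cfg$preset == "standard" && cfg$angle_count <= 8L)
    stop("standard preset requires more than 8 angular views")
  ch <- cfg$enc_channels; f <- cfg$feat_dim
  p <- list(
    enc1a = init_conv3(1L, ch[1], 3L), enc1b = init_conv3(ch[1], ch[1], 3L),
    enc2a = init_conv3(ch[1], ch[2], 3L), enc2b = init_conv3(ch[2], ch[2], 3L),
    enc3a = init_conv3(ch[2], ch[3], 3L), enc3b = init_conv3(ch[3], ch[3], 3L),
    mid = init_conv3(ch[3], f, 3L),
    t_ang = lapply(seq_len(cfg$tf_depth), function(i)
      init_tf_block(f, cfg$tf_mlp_ratio)),
    t_spa = lapply(seq_len(cfg$tf_depth), function(i)
      init_tf_block(f, cfg$tf_mlp_ratio)),
    back = init_conv3(f, ch[3], 3L),
    dec3a = init_conv3(2L * ch[3], ch[3], 3L), dec3b = init_conv3(ch[3], ch[3], 3L),
    dec2a = init_conv3(ch[3] + ch[2], ch[2], 3L), dec2b = init_conv3(ch[2], ch[2], 3L),
    dec1a = init_conv3(ch[2] + ch[1], ch[1], 3L), dec1b = init_conv3(ch[1], ch[1], 3L),
    out = init_conv3(ch[1], 1L, 1L, zero = TRUE))
  structure(list(params = p, cfg = cfg), class = "lf_subnetwork")
}

conv3_block <- function(x, cv, slope) ad_lrelu(ad_conv3(x, cv$w, cv$b, cv$k), slope)

sinusoid_posenc <- function(dim, S) {
  pos <- seq_len(S) - 1
  half <- ceiling(dim / 2)
  freq <- 10000^(-(2 * (seq_len(half) - 1)) / dim)
  ang <- outer(freq, pos)
  p <- matrix(0, dim, S)
  odd <- seq(1L, dim, by = 2L)
  evn <- seq(2L, dim, by = 2L)
  p[odd, ] <- sin(ang)[seq_along(odd), ]
  if (length(evn)) p[evn, ] <- cos(ang)[seq_along(evn), ]
  p
}

# Separable 2D positional embedding for (h, w) token grids: the first half
# of the feature dims encodes the row, the second half the column, so the
# pattern seen by each token is independent of the overall image size
# (train and inference resolutions may differ).
sinusoid_posenc2d <- function(dim, h, w) {
  dh <- dim %/% 2L
  pr <- sinusoid_posenc(dh, h)                 # (dh, h)
  pc <- sinusoid_posenc(dim - dh, w)           # (dim - dh, w)
  out <- matrix(0, dim, h * w)
  out[seq_len(dh), ] <- pr[, rep(seq_len(h), w)]
  out[dh + seq_len(dim - dh), ] <- pc[, rep(seq_len(w), each = h)]
  out
}

tf_block_forward <- function(x, blk, S, B, heads) {
  h <- ad_layernorm(x, blk$ln1$g, blk$ln1$b)
  q <- ad_lin(blk$q$W, h, blk$q$b)
  k <- ad_lin(blk$k$W, h, blk$k$b)
  v <- ad_lin(blk$v$W, h, blk$v$b)
  a <- ad_attention(q, k, v, S, B, heads)
  x <- ad_add(x, ad_lin(blk$o$W, a, blk$o$b))
  h <- ad_layernorm(x, blk$ln2$g, blk$ln2$b)
  ad_add(x, ad_lin(blk$m2$W, ad_gelu(ad_lin(blk$m1$W, h, blk$m1$b)), blk$m2$b))
}

#' Run an EPI sub-network forward
#'
#' @param net an `lf_subnetwork`.
#' @param x 3D array or `ad_node` of shape `(outer-spatial, angle,
#'   inner-spatial)` -- an EPI (sub-)stack. Output has identical shape.
#' @return An `ad_node` (use `ad_value()` for the plain array).
#' @export
forward_subnetwork <- function(net, x) {
  if (!inherits(x, "ad_node")) x <- ad_const(x)
  p <- net$params; cfg <- net$cfg
  sl <- cfg$lrelu_slope
  d0 <- dim(x$v)
  if (d0[2] <= 8L)
    stop(sprintf("angular extent must exceed 8 views, got %d", d0[2]))
  x4 <- ad_reshape(x, c(1L, d0))
  e1 <- conv3_block(conv3_block(x4, p$enc1a, sl), p$enc1b, sl)
  p1 <- ad_maxpool3(e1)
  e2 <- conv3_block(conv3_block(p1, p$enc2a, sl), p$enc2b, sl)
  p2 <- ad_maxpool3(e2)
  e3 <- conv3_block(conv3_block(p2, p$enc3a, sl), p$enc3b, sl)
  p3 <- ad_maxpool3(e3)
  m <- conv3_block(p3, p$mid, sl)
  dm <- dim(m$v)                       # (F, d3, A3, s3)
  f <- dm[1]; d3 <- dm[2]; A3 <- dm[3]; s3 <- dm[4]
  # temporal transformer: tokens along the angular axis
  t <- ad_permute(m, c(1L, 3L, 2L, 4L))          # (F, A3, d3, s3)
  t <- ad_reshape(t, c(f, A3 * d3 * s3))
  pe <- sinusoid_posenc(f, A3)
  t <- ad_add(t, ad_const(pe[, rep(seq_len(A3), d3 * s3)]))
  for (blk in p$t_ang)
    t <- tf_block_forward(t, blk, A3, d3 * s3, cfg$tf_heads)
  t <- ad_reshape(t, c(f, A3, d3, s3))
  t <- ad_permute(t, c(1L, 3L, 2L, 4L))          # (F, d3, A3, s3)
  # spatial transformer: tokens over (outer, inner) spatial positions
  s <- ad_permute(t, c(1L, 2L, 4L, 3L))          # (F, d3, s3, A3)
  s <- ad_reshape(s, c(f, d3 * s3 * A3))
  pe2 <- sinusoid_posenc2d(f, d3, s3)
  s <- ad_add(s, ad_const(pe2[, rep(seq_len(d3 * s3), A3)]))
  for (blk in p$t_spa)
    s <- tf_block_forward(s, blk, d3 * s3, A3, cfg$tf_heads)
  s <- ad_reshape(s, c(f, d3, s3, A3))
  s <- ad_permute(s, c(1L, 2L, 4L, 3L))          # (F, d3, A3, s3)
  b3 <- conv3_block(s, p$back, sl)
  u3 <- ad_upsample3(b3, dim(e3$v)[2:4])
  d3n <- conv3_block(conv3_block(ad_cat(u3, e3, 1L), p$dec3a, sl), p$dec3b, sl)
  u2 <- ad_upsample3(d3n, dim(e2$v)[2:4])
  d2n <- conv3_block(conv3_block(ad_cat(u2, e2, 1L), p$dec2a, sl), p$dec2b, sl)
  u1 <- ad_upsample3(d2n, dim(e1$v)[2:4])
  d1n <- conv3_block(conv3_block(ad_cat(u1, e1, 1L), p$dec1a, sl), p$dec1b, sl)
  res <- ad_conv3(d1n, p$out$w, p$out$b, 1L)
  y <- ad_add(x4, res)
  ad_reshape(y, d0)
}

# ---- fusion module -------------------------------------------------------

#' Build the attention-based fusion module
#'
#' Consumes the two sub-network outputs interleaved along the channel
#' (angular) axis, shape `(2A, h, w)`, and produces `(A, h, w)`. Route 1
#' embeds tokens (1x1 convolution to the fusion width plus sinusoidal
#' positional embedding), runs eight residual window-transformer blocks,
#' un-embeds, and applies a double convolution along the angular axis
#' reducing `2A -> A`. Route 2 applies the *same weight-shared* double
#' convolution to the raw input and refines it with five
#' convolution-block-attention modules (each applying channel attention --
#' spatial max + average pooling through a shared two-layer bottleneck --
#' and spatial attention -- channel-wise average and max, concatenated,
#' reduced by a 7x7 convolution -- three times, attention maps multiplied
#' onto the features). The two routes are combined by element-wise mean and
#' added to the per-pair mean of the interleaved input (residual path; the
#' reducing convolution is zero-initialized, so a fresh module averages its
#' two inputs).
#'
#' @param cfg an [lf_network_config()].
#' @return An object of class `lf_fusion`.
#' @export
build_fusion <- function(cfg) {
  A <- cfg$angle_count; D <- cfg$fusion_dim
  p <- list(
    embed = init_lin(2L * A, D),
    blocks = lapply(seq_len(cfg$fusion_blocks), function(i)
      init_tf_block(D, cfg$fusion_mlp_ratio)),
    ln_final = init_ln(D),
    unembed = init_lin(D, 2L * A),
    dc1 = init_conv2(2L * A, 2L * A, 3L),
    dc2 = init_conv2(2L * A, A, 3L, zero = TRUE),
    cbam = lapply(seq_len(cfg$cbam_blocks), function(i) {
      cr <- max(1L, A %/% cfg$cbam_reduction)
      list(ca = lapply(seq_len(cfg$cbam_inner), function(j)
             list(W1 = init_lin(A, cr), W2 = init_lin(cr, A))),
           sa = lapply(seq_len(cfg$cbam_inner), function(j)
             init_conv2(2L, 1L, 7L)))
    }))
  structure(list(params = p, cfg = cfg), class = "lf_fusion")
}

win_partition_perm <- function(h, w, wy, wx) {
  ord <- integer(h * w); kk <- 0L
  for (bx in seq_len(w %/% wx)) for (by in seq_len(h %/% wy))
    for (jx in seq_len(wx)) for (jy in seq_len(wy)) {
      kk <- kk + 1L
      ord[kk] <- ((by - 1L) * wy + jy) + h * (((bx - 1L) * wx + jx) - 1L)
    }
  ord
}

largest_divisor_leq <- function(n, m) {
  for (d in seq(min(n, m), 1L)) if (n %% d == 0L) return(d)
  1L
}

cbam_forward <- function(x, mod, slope) {
  # x: (A, h, w)
  C <- dim(x$v)[1]
  for (ca in mod$ca) {
    avg <- ad_reshape(ad_mean_spatial(x), c(C, 1L))
    mx <- ad_reshape(ad_max_spatial(x), c(C, 1L))
    shared <- function(v) ad_lin(ca$W2$W, ad_lrelu(ad_lin(ca$W1$W, v, ca$W1$b), slope), ca$W2$b)
    att <- ad_sigmoid(ad_add(shared(avg), shared(mx)))
    x <- ad_mul_channel(x, ad_reshape(att, C))
  }
  for (sa in mod$sa) {
    d <- dim(x$v)
    avg <- ad_reshape(ad_mean_channels(x), c(1L, d[2], d[3]))
    mx <- ad_reshape(ad_max_channels(x), c(1L, d[2], d[3]))
    two <- ad_cat(avg, mx, 1L)
    att <- ad_sigmoid(ad_conv2(two, sa$w, sa$b, sa$k))
    x <- ad_mul_spatial(x, ad_reshape(att, dim(att$v)[2:3]))
  }
  x
}

#' Run the fusion module forward
#'
#' @param fus an `lf_fusion`.
#' @param z 3D array or `ad_node` of shape `(2A, h, w)`: the interleaved
#'   sub-network outputs.
#' @return An `ad_node` of shape `(A, h, w)`.
#' @export
forward_fusion <- function(fus, z) {
  if (!inherits(z, "ad_node")) z <- ad_const(z)
  p <- fus$params; cfg <- fus$cfg
  sl <- cfg$lrelu_slope
  d <- dim(z$v)
  A <- cfg$angle_count
  if (d[1] != 2L * A)
    stop(sprintf("fusion expects %d interleaved channels, got %d", 2L * A, d[1]))
  h <- d[2]; w <- d[3]
  odd <- seq(1L, 2L * A, by = 2L); evn <- seq(2L, 2L * A, by = 2L)
  base <- ad_scale(ad_add(ad_index(z, list(odd, seq_len(h), seq_len(w))),
                          ad_index(z, list(evn, seq_len(h), seq_len(w)))), 0.5)
  # route 1: embedded tokens -> residual window-transformer blocks
  t <- ad_reshape(z, c(2L * A, h * w))
  t <- ad_lin(p$embed$W, t, p$embed$b)
  t <- ad_add(t, ad_const(sinusoid_posenc2d(cfg$fusion_dim, h, w)))
  wy <- largest_divisor_leq(h, cfg$fusion_window)
  wx <- largest_divisor_leq(w, cfg$fusion_window)
  perm <- win_partition_perm(h, w, wy, wx)
  t <- ad_index(t, list(seq_len(cfg$fusion_dim), perm))
  S <- wy * wx; B <- (h %/% wy) * (w %/% wx)
  for (blk in p$blocks)
    t <- tf_block_forward(t, blk, S, B, cfg$fusion_heads)
  # final normalization: keeps per-token feature scale independent of the
  # inference resolution (training runs at half resolution)
  t <- ad_layernorm(t, p$ln_final$g, p$ln_final$b)
  t <- ad_index(t, list(seq_len(cfg$fusion_dim), order(perm)))
  t <- ad_lin(p$unembed$W, t, p$unembed$b)
  t <- ad_reshape(t, c(2L * A, h, w))
  dconv <- function(x) ad_conv2(ad_lrelu(ad_conv2(x, p$dc1$w, p$dc1$b, p$dc1$k), sl),
                                p$dc2$w, p$dc2$b, p$dc2$k)
  r1 <- dconv(t)
  # route 2: shared double conv then CBAM refinement
  r2 <- dconv(z)
  for (mod in p$cbam) r2 <- cbam_forward(r2, mod, sl)
  delta <- switch(cfg$route_merge,
                  mean = ad_scale(ad_add(r1, r2), 0.5),
                  sum = ad_add(r1, r2),
                  stop("unknown route_merge"))
  ad_add(base, delta)
}

#' Interleave the two sub-network outputs for fusion
#'
#' Channels alternate between the x-s and y-t routes: output channel 1 is
#' `y_xs` view 1, channel 2 is `y_yt` view 1, channel 3 is `y_xs` view 2,
#' and so on, pairing the same angular view from the two routes.
#'
#' @param y_xs,y_yt arrays or `ad_node`s of shape `(A, h, w)` with matching
#'   angular ordering.
#' @return An `ad_node` of shape `(2A, h, w)`.
#' @export
interleave_fusion_input <- function(y_xs, y_yt) {
  if (!inherits(y_xs, "ad_node")) y_xs <- ad_const(y_xs)
  if (!inherits(y_yt, "ad_node")) y_yt <- ad_const(y_yt)
  da <- dim(y_xs$v); db <- dim(y_yt$v)
  if (!all(da == db)) stop("interleave inputs must share one shape")
  A <- da[1]
  z <- ad_cat(y_xs, y_yt, 1L)
  perm <- as.vector(rbind(seq_len(A), A + seq_len(A)))
  ad_index(z, list(perm, seq_len(da[2]), seq_len(da[3])))
}

#' @rdname interleave_fusion_input
#' @param z interleaved array or node `(2A, h, w)`.
#' @return `deinterleave_fusion_input`: `list(y_xs, y_yt)` of values.
#' @export
deinterleave_fusion_input <- function(z) {
  v <- if (inherits(z, "ad_node")) z$v else z
  A <- dim(v)[1] %/% 2L
  list(y_xs = v[seq(1L, 2L * A, by = 2L), , , drop = FALSE],
       y_yt = v[seq(2L, 2L * A, by = 2L), , , drop = FALSE])
}

# ---- model assembly and parameter count ---------------------------------

#' Build the full denoising model set
#'
#' @param cfg an [lf_network_config()].
#' @param seed RNG seed for weight initialization.
#' @return `list(xs, yt, fusion, cfg)`: the x-s and y-t sub-networks and the
#'   fusion module.
#' @export
build_lf_models <- function(cfg = lf_network_config(), seed = 1L) {
  set.seed(seed)
  models <- list(xs = build_subnetwork(cfg), yt = build_subnetwork(cfg),
                 fusion = build_fusion(cfg), cfg = cfg)
  class(models) <- "lf_models"
  models
}

flatten_params <- function(x) {
  if (inherits(x, "ad_node")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, flatten_params)))
  list()
}

model_params <- function(models) {
  if (inherits(models, "lf_models"))
    flatten_params(list(models$xs$params, models$yt$params, models$fusion$params))
  else flatten_params(models$params)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars over every weight, bias, gain and
#' embedding array of the model (or of one module).
#'
#' @param models an `lf_models`, `lf_subnetwork` or `lf_fusion`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(models) {
  sum(vapply(model_params(models), function(p) length(p$v), numeric(1)))
}

#' @export
print.lf_models <- function(x, ...) {
  cat(sprintf("<lf_models %s: A=%d, %.2f M trainable parameters>\n",
              x$cfg$preset, x$cfg$angle_count, count_parameters(x) / 1e6))
  invisible(x)
}
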