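# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Central finite-difference gradient of a scalar function of an array.
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# A small light field with distinct values per (u, v, y, x).
coded_lightfield <- function(U = 3L, V = 3L, H = 8L, W = 8L) {
  a <- array(0, c(U, V, H, W))
  for (u in seq_len(U)) for (v in seq_len(V))
    for (y in seq_len(H)) for (x in seq_len(W))
      a[u, v, y, x] <- u * 1e5 + v * 1e4 + y * 1e2 + x
  lightfield(a)
}

# Desk-scale simulated acquisition shared by several test files.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      proj <- lf_projector(c(3L, 3L), 16L, kappa = 0.4)
      cache <<- simulate_lightfield("beads", c(16L, 40L, 40L), n_objects = 6L,
                                    seed = 5L, proj = proj,
                                    np = noise_params(100, gauss_var = 5, seed = 6L))
    }
    cache
  }
})

# Micro network configuration: fast enough for per-test training.
micro_config <- function(angle_count = 9L) {
  lf_network_config("tiny", angle_count = angle_count,
                    enc_channels = c(2L, 4L, 8L), feat_dim = 16L,
                    tf_depth = 1L, tf_heads = 2L, tf_mlp_ratio = 2L,
                    fusion_dim = 16L, fusion_blocks = 1L, fusion_heads = 2L,
                    fusion_window = 4L, fusion_mlp_ratio = 2L,
                    cbam_blocks = 1L, cbam_inner = 1L)
}
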