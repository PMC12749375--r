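# ------------------------------------------------------------------------
# Simplified iterative tomography: volume <-> light-field forward/backward
# geometric projections and a multiplicative sequential-view reconstruction
# (Richardson-Lucy style) from a uniform initial estimate.
# ------------------------------------------------------------------------

#' Forward projection (volume to light field)
#'
#' Identical contract to [project_volume()]; exposed under the
#' reconstruction vocabulary (used to estimate the reconstruction error).
#'
#' @inheritParams project_volume
#' @export
forward_project <- function(vol, proj, bit_depth = 16L)
  project_volume(vol, proj, bit_depth)

#' Backward projection (light field to volume)
#'
#' The exact adjoint of [forward_project()]: each view is translated by the
#' inverse per-plane disparity and summed into the corresponding depth
#' plane, satisfying `<P v, l> == <v, P^T l>`.
#'
#' @param lf a `lightfield` whose angular shape matches the projector.
#' @param proj an [lf_projector()].
#' @return A 3D array `(Z, Y, X)` of class `volume`.
#' @export
back_project <- function(lf, proj) {
  d <- dim(lf$data)
  if (!all(d[1:2] == proj$angular_shape))
    stop(sprintf("projector angular shape (%d, %d) does not match light field (%d, %d)",
                 proj$angular_shape[1], proj$angular_shape[2], d[1], d[2]))
  vol <- array(0, c(proj$n_planes, d[3], d[4]))
  for (z in seq_len(proj$n_planes)) {
    dz <- disparity_at(proj, z)
    acc <- matrix(0, d[3], d[4])
    for (u in seq_len(d[1])) for (v in seq_len(d[2])) {
      view <- lf$data[u, v, , ]
      if (dz == 0) acc <- acc + view
      else acc <- acc + shift_bilinear(view, -dz * (v - proj$v0),
                                       -dz * (u - proj$u0))
    }
    vol[z, , ] <- acc
  }
  structure(vol, class = c("volume", class(vol)))
}

# Center-outward spiral ordering of angular views (distance from the
# central view, ties broken by polar angle).
view_order_spiral <- function(U, V) {
  u0 <- (U + 1) / 2; v0 <- (V + 1) / 2
  g <- expand.grid(u = seq_len(U), v = seq_len(V))
  r <- sqrt((g$u - u0)^2 + (g$v - v0)^2)
  th <- atan2(g$v - v0, g$u - u0)
  g[order(r, th), , drop = FALSE]
}

#' Iterative tomographic reconstruction
#'
#' Multiplicative update sweeping the angular views sequentially from a
#' uniform initial volume: for each view `(u, v)` in center-outward spiral
#' order, the current estimate is forward-projected to that view, the
#' measured view is divided by the prediction (epsilon-guarded), the ratio
#' is back-projected and normalized by the back-projection of a unit view,
#' and the volume is multiplied by the correction. Non-negativity is
#' preserved at every iteration.
#'
#' @param lf a non-negative `lightfield`.
#' @param proj an [lf_projector()] matching the angular shape.
#' @param n_iter number of full sweeps over the views (default 10).
#' @param eps_rel ratio guard relative to the maximum light-field intensity
#'   (default 1e-8).
#' @return A 3D array `(Z, Y, X)` of class `volume`.
#' @export
reconstruct_volume <- function(lf, proj, n_iter = 10L, eps_rel = 1e-8) {
  stopifnot(n_iter >= 1L)
  d <- dim(lf$data)
  if (!all(d[1:2] == proj$angular_shape))
    stop("projector angular shape does not match light field")
  if (any(lf$data < 0)) stop("light field must be non-negative")
  mx <- max(lf$data)
  if (mx <= 0) stop("cannot reconstruct an all-zero light field")
  eps <- eps_rel * mx
  Z <- proj$n_planes
  vol <- array(mean(lf$data) / Z, c(Z, d[3], d[4]))     # uniform init
  ord <- view_order_spiral(d[1], d[2])
  ones <- matrix(1, d[3], d[4])
  for (it in seq_len(n_iter)) {
    for (k in seq_len(nrow(ord))) {
      u <- ord$u[k]; v <- ord$v[k]
      pred <- matrix(0, d[3], d[4])
      for (z in seq_len(Z)) {
        dz <- disparity_at(proj, z)
        pred <- pred + if (dz == 0) vol[z, , ]
        else shift_bilinear(vol[z, , ], dz * (v - proj$v0), dz * (u - proj$u0))
      }
      ratio <- lf$data[u, v, , ] / pmax(pred, eps)
      for (z in seq_len(Z)) {
        dz <- disparity_at(proj, z)
        if (dz == 0) {
          corr <- ratio
          norm <- ones
        } else {
          corr <- shift_bilinear(ratio, -dz * (v - proj$v0), -dz * (u - proj$u0))
          norm <- shift_bilinear(ones, -dz * (v - proj$v0), -dz * (u - proj$u0))
        }
        vol[z, , ] <- vol[z, , ] * corr / pmax(norm, 1e-6)
      }
    }
  }
  structure(vol, class = c("volume", class(vol)))
}

#' Data-fidelity residual of a volume estimate
#'
#' Root-mean-square difference between the forward projection of `vol` and
#' the measured light field; used to audit convergence of
#' [reconstruct_volume()].
#'
#' @param vol a volume estimate.
#' @param lf the measured `lightfield`.
#' @param proj the projector.
#' @return A single number.
#' @export
reconstruction_residual <- function(vol, lf, proj) {
  pred <- forward_project(vol, proj, bit_depth = lf$bit_depth)
  sqrt(mean((pred$data - lf$data)^2))
}
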