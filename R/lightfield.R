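# ------------------------------------------------------------------------
# 4D spatial-angular light fields and their rearrangements: central-view
# selection, angular padding, bidirectional EPI traversal, spatial patching.
# ------------------------------------------------------------------------

#' Construct a light field
#'
#' A light field is a 4D intensity array indexed `(u, v, y, x)`: `u`/`v` are
#' the horizontal/vertical angular indices and `y`/`x` the spatial pixel
#' coordinates. Intensities are camera digital numbers in
#' `[0, 2^bit_depth - 1]`. Acquisitions with a flat (non-square) angular
#' layout, such as the 13 sequential illumination angles of two-photon
#' synthetic-aperture microscopy, use an angular shape of `(A, 1)`.
#'
#' @param data 4D numeric array `(U, V, H, W)`, or a 3D array `(A, H, W)`
#'   which is treated as angular shape `(A, 1)`.
#' @param bit_depth camera bit depth (8 or 16).
#' @param system_tag one of `"LFM"`, `"sLFM"`, `"2pSAM"`.
#' @param pad_flags logical vector over flattened angular index marking
#'   views added by [pad_angular_views()] (stripped after inference).
#' @return An object of class `lightfield`.
#' @export
lightfield <- function(data, bit_depth = 16L, system_tag = "sLFM",
                       pad_flags = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1], 1L, dim(data)[2:3])
  stopifnot(length(dim(data)) == 4L)
  stopifnot(bit_depth %in% c(8L, 16L))
  system_tag <- match.arg(system_tag, c("LFM", "sLFM", "2pSAM"))
  d <- dim(data)
  if (is.null(pad_flags)) pad_flags <- rep(FALSE, d[1] * d[2])
  stopifnot(length(pad_flags) == d[1] * d[2])
  structure(list(data = data, bit_depth = as.integer(bit_depth),
                 system_tag = system_tag, pad_flags = pad_flags),
            class = "lightfield")
}

#' @export
print.lightfield <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lightfield %s: %d x %d angular, %d x %d spatial, %d-bit%s>\n",
              x$system_tag, d[1], d[2], d[3], d[4], x$bit_depth,
              if (any(x$pad_flags)) sprintf(", %d padded views", sum(x$pad_flags)) else ""))
  invisible(x)
}

#' @rdname lightfield
#' @param lf a `lightfield`.
#' @export
angular_shape <- function(lf) dim(lf$data)[1:2]

#' @rdname lightfield
#' @export
spatial_shape <- function(lf) dim(lf$data)[3:4]

#' @rdname lightfield
#' @export
n_views <- function(lf) prod(dim(lf$data)[1:2])

validate_lightfield <- function(lf) {
  stopifnot(inherits(lf, "lightfield"))
  if (any(lf$data < 0)) stop("light field contains negative intensities")
  mx <- 2^lf$bit_depth - 1
  if (any(lf$data > mx))
    stop(sprintf("light field exceeds the %d-bit range [0, %d]", lf$bit_depth, mx))
  invisible(lf)
}

#' Retain the centered square sub-grid of angular views
#'
#' Scanning light-field microscopes record a 13 x 13 angular grid; the
#' denoiser operates on the 81 central views (9 x 9), which carry most of
#' the signal energy and keep training and inference fast.
#'
#' @param lf a [lightfield()] with a square angular grid.
#' @param side odd integer, the retained grid side (default 9).
#' @return A `lightfield` with `side^2` views; idempotent when the input
#'   already has `side x side` views.
#' @export
select_central_views <- function(lf, side = 9L) {
  d <- dim(lf$data)
  if (side %% 2L == 0L)
    stop(sprintf("`side` must be odd, got %d", side))
  if (d[1] != d[2])
    stop(sprintf("angular grid must be square, got %d x %d", d[1], d[2]))
  if (side > d[1])
    stop(sprintf("`side` (%d) exceeds angular grid side U = V = %d", side, d[1]))
  if (side == d[1]) return(lf)
  off <- (d[1] - side) %/% 2L
  keep <- off + seq_len(side)
  lightfield(lf$data[keep, keep, , , drop = FALSE], lf$bit_depth, lf$system_tag)
}

#' Pad the flattened angular axis to a target view count
#'
#' Thirteen-view acquisitions are padded to 16 views before entering the
#' network (whose pooling stages require the angular extent to be
#' reducible); padded views replicate the last real view and are flagged so
#' [strip_padded_views()] removes them bit-exactly after inference.
#'
#' @param lf a `lightfield` with flat angular layout `(A, 1)`.
#' @param target integer, total views after padding (default 16).
#' @return A `lightfield` with `target` views and `pad_flags` set.
#' @export
pad_angular_views <- function(lf, target = 16L) {
  d <- dim(lf$data)
  A <- d[1] * d[2]
  if (A > target)
    stop(sprintf("view count %d exceeds padding target %d", A, target))
  if (A == target) return(lf)
  if (d[2] != 1L) stop("angular padding requires a flat (A, 1) angular layout")
  extra <- target - A
  pad <- lf$data[rep(d[1], extra), 1L, , , drop = FALSE]
  out <- array(0, c(target, 1L, d[3], d[4]))
  out[seq_len(A), 1L, , ] <- lf$data
  out[A + seq_len(extra), 1L, , ] <- pad
  lightfield(out, lf$bit_depth, lf$system_tag,
             pad_flags = c(rep(FALSE, A), rep(TRUE, extra)))
}

#' @rdname pad_angular_views
#' @export
strip_padded_views <- function(lf) {
  if (!any(lf$pad_flags)) return(lf)
  d <- dim(lf$data)
  stopifnot(d[2] == 1L)
  keep <- which(!lf$pad_flags)
  lightfield(lf$data[keep, 1L, , , drop = FALSE], lf$bit_depth, lf$system_tag)
}

#' Angular traversal order for EPI construction
#'
#' Serializes the 2D angular grid to the single angle axis of an EPI stack.
#' For the `"x-s"` orientation the horizontal angular coordinate `u` varies
#' fastest; for `"y-t"` the vertical coordinate `v` does. The default
#' serpentine (boustrophedon) scheme reverses direction on alternate rows or
#' columns so adjacent positions on the angle axis always differ by a single
#' angular step, maximizing EPI continuity; `"raster"` is plain
#' row/column-major order. Flat `(A, 1)` layouts traverse forward for
#' `"x-s"` and in reverse for `"y-t"` (the two traversal directions).
#'
#' @param U,V angular grid extents.
#' @param orientation `"x-s"` or `"y-t"`.
#' @param scheme `"serpentine"` (default) or `"raster"`.
#' @return Integer matrix `(A, 2)` of 1-based `(u, v)` indices.
#' @export
angular_traversal <- function(U, V, orientation = c("x-s", "y-t"),
                              scheme = c("serpentine", "raster")) {
  orientation <- match.arg(orientation)
  scheme <- match.arg(scheme)
  if (U == 1L || V == 1L) {
    a <- seq_len(U * V)
    if (orientation == "y-t") a <- rev(a)
    if (V == 1L) return(cbind(u = a, v = rep(1L, length(a))))
    return(cbind(u = rep(1L, length(a)), v = a))
  }
  out <- matrix(0L, U * V, 2L, dimnames = list(NULL, c("u", "v")))
  k <- 0L
  if (orientation == "x-s") {
    for (v in seq_len(V)) {
      us <- seq_len(U)
      if (scheme == "serpentine" && v %% 2L == 0L) us <- rev(us)
      for (u in us) { k <- k + 1L; out[k, ] <- c(u, v) }
    }
  } else {
    for (u in seq_len(U)) {
      vs <- seq_len(V)
      if (scheme == "serpentine" && u %% 2L == 0L) vs <- rev(vs)
      for (v in vs) { k <- k + 1L; out[k, ] <- c(u, v) }
    }
  }
  out
}

#' Rearrange a light field into an EPI stack
#'
#' An epipolar-plane-image (EPI) stack is a 3D array mixing one spatial and
#' the serialized angular axis. The `"x-s"` orientation yields layout
#' `(H, A, W)` (outer spatial = image rows y; each slice `[y, , ]` is an
#' x-s EPI); `"y-t"` yields `(W, A, H)` (outer spatial = image columns x).
#' The traversal is carried on the object so [epi_stack_to_lf()] is a
#' bit-exact inverse.
#'
#' @inheritParams angular_traversal
#' @param lf a `lightfield` (views already selected/padded).
#' @return An object of class `epi_stack`.
#' @export
lf_to_epi_stack <- function(lf, orientation = c("x-s", "y-t"),
                            scheme = c("serpentine", "raster")) {
  orientation <- match.arg(orientation)
  scheme <- match.arg(scheme)
  d <- dim(lf$data)
  trav <- angular_traversal(d[1], d[2], orientation, scheme)
  A <- nrow(trav)
  flat <- trav[, 1] + d[1] * (trav[, 2] - 1L)
  x <- lf$data
  dim(x) <- c(d[1] * d[2], d[3], d[4])       # (A_flat, H, W)
  x <- x[flat, , , drop = FALSE]             # traversal order
  if (orientation == "x-s") {
    data <- aperm(x, c(2L, 1L, 3L))          # (H, A, W)
  } else {
    data <- aperm(x, c(3L, 1L, 2L))          # (W, A, H)
  }
  structure(list(data = data, orientation = orientation,
                 traversal = trav, angular_shape = d[1:2],
                 scheme = scheme, bit_depth = lf$bit_depth,
                 system_tag = lf$system_tag, pad_flags = lf$pad_flags),
            class = "epi_stack")
}

#' @export
print.epi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epi_stack %s: %d x %d x %d (outer, angle, inner), %s traversal>\n",
              x$orientation, d[1], d[2], d[3], x$scheme))
  invisible(x)
}

#' @rdname lf_to_epi_stack
#' @param epi an `epi_stack`.
#' @export
epi_stack_to_lf <- function(epi) {
  stopifnot(inherits(epi, "epi_stack"))
  d <- dim(epi$data)
  ash <- epi$angular_shape
  trav <- epi$traversal
  if (nrow(trav) != d[2] || nrow(trav) != prod(ash) ||
      any(trav[, 1] < 1L) || any(trav[, 1] > ash[1]) ||
      any(trav[, 2] < 1L) || any(trav[, 2] > ash[2]) ||
      anyDuplicated(trav[, 1] + ash[1] * (trav[, 2] - 1L)) > 0L)
    stop("inconsistent or corrupted traversal_order for this EPI stack")
  if (epi$orientation == "x-s") {
    x <- aperm(epi$data, c(2L, 1L, 3L))      # (A, H, W)
  } else {
    x <- aperm(epi$data, c(2L, 3L, 1L))      # (A, H, W)
  }
  flat <- trav[, 1] + ash[1] * (trav[, 2] - 1L)
  inv <- order(flat)
  x <- x[inv, , , drop = FALSE]
  dim(x) <- c(ash[1], ash[2], dim(x)[2], dim(x)[3])
  lightfield(x, epi$bit_depth, epi$system_tag, pad_flags = epi$pad_flags)
}

# ---- spatial patching -----------------------------------------------------

patch_origins <- function(extent, patch, overlap) {
  if (extent <= patch) return(1L)
  step <- patch - overlap
  o <- seq(1L, extent - patch + 1L, by = step)
  if (o[length(o)] != extent - patch + 1L) o <- c(o, extent - patch + 1L)
  as.integer(o)
}

reflect_pad_spatial <- function(x, ph, pw) {
  # x: (U, V, H, W); pad trailing spatial edges by reflection
  d <- dim(x)
  if (ph > 0L) {
    if (ph > d[3] - 1L) stop("input too small to reflection-pad")
    mirror <- x[, , d[3] - seq_len(ph), , drop = FALSE]
    x <- .cat_arrays(x, mirror, 3L)
  }
  d <- dim(x)
  if (pw > 0L) {
    if (pw > d[4] - 1L) stop("input too small to reflection-pad")
    mirror <- x[, , , d[4] - seq_len(pw), drop = FALSE]
    x <- .cat_arrays(x, mirror, 4L)
  }
  x
}

#' Extract overlapping spatial patches
#'
#' Tiles the spatial plane with `patch_size x patch_size` windows (default
#' 128 px as used for training and inference) overlapping by `overlap`
#' pixels; the final row/column of origins is shifted so every pixel is
#' covered. Inputs smaller than the patch are reflection-padded and cropped
#' back by [stitch_patches()].
#'
#' @param lf a `lightfield`.
#' @param patch_size even integer, spatial patch side.
#' @param overlap overlap in pixels between adjacent patches.
#' @return `list(patches = <list of (U,V,ps,ps) arrays>, grid = <patch_grid>)`.
#' @export
extract_patches <- function(lf, patch_size = 128L, overlap = 16L) {
  stopifnot(patch_size %% 2L == 0L, overlap >= 0L, overlap < patch_size)
  d <- dim(lf$data)
  x <- lf$data
  ph <- max(0L, patch_size - d[3])
  pw <- max(0L, patch_size - d[4])
  if (ph > 0L || pw > 0L) x <- reflect_pad_spatial(x, ph, pw)
  dp <- dim(x)
  oy <- patch_origins(dp[3], patch_size, overlap)
  ox <- patch_origins(dp[4], patch_size, overlap)
  grid <- structure(list(patch_size = patch_size, overlap = overlap,
                         origins = expand.grid(y = oy, x = ox),
                         padded_shape = dp[3:4], full_shape = d[3:4]),
                    class = "patch_grid")
  patches <- vector("list", nrow(grid$origins))
  for (i in seq_len(nrow(grid$origins))) {
    y0 <- grid$origins$y[i]; x0 <- grid$origins$x[i]
    patches[[i]] <- x[, , y0 + seq_len(patch_size) - 1L,
                      x0 + seq_len(patch_size) - 1L, drop = FALSE]
  }
  list(patches = patches, grid = grid)
}

#' Stitch patches back into a light field
#'
#' Overlapping regions are blended with uniform averaging: each patch
#' contributes weight 1 and the accumulated image is divided by the per-pixel
#' weight sum, so the weights form a partition of unity. Cutting patches and
#' stitching them unchanged reproduces the input exactly.
#'
#' @param patches list of `(U, V, ps, ps)` arrays matching `grid`.
#' @param grid a `patch_grid` from [extract_patches()].
#' @param template a `lightfield` supplying bit depth and metadata.
#' @return A `lightfield`.
#' @export
stitch_patches <- function(patches, grid, template) {
  ps <- grid$patch_size
  n <- nrow(grid$origins)
  if (length(patches) != n)
    stop(sprintf("expected %d patches for this grid, got %d", n, length(patches)))
  d4 <- dim(patches[[1]])
  acc <- array(0, c(d4[1], d4[2], grid$padded_shape))
  wt <- array(0, grid$padded_shape)
  for (i in seq_len(n)) {
    y0 <- grid$origins$y[i]; x0 <- grid$origins$x[i]
    ys <- y0 + seq_len(ps) - 1L; xs <- x0 + seq_len(ps) - 1L
    acc[, , ys, xs] <- acc[, , ys, xs, drop = FALSE] + patches[[i]]
    wt[ys, xs] <- wt[ys, xs] + 1
  }
  if (any(wt == 0)) stop("patch grid does not cover the full spatial extent")
  acc <- acc / rep(as.vector(wt), each = d4[1] * d4[2])[
    seq_len(length(acc))]
  fs <- grid$full_shape
  out <- acc[, , seq_len(fs[1]), seq_len(fs[2]), drop = FALSE]
  lightfield(pmax(out, 0), template$bit_depth, template$system_tag,
             pad_flags = template$pad_flags)
}

#' Partition-of-unity stitch weights
#'
#' Returns the per-pixel normalized weight total (identically 1 when the
#' grid covers the plane), used to audit the blending.
#' @param grid a `patch_grid`.
#' @return Matrix of weight sums after normalization.
#' @export
stitch_weight_map <- function(grid) {
  wt <- array(0, grid$padded_shape)
  ps <- grid$patch_size
  for (i in seq_len(nrow(grid$origins))) {
    ys <- grid$origins$y[i] + seq_len(ps) - 1L
    xs <- grid$origins$x[i] + seq_len(ps) - 1L
    wt[ys, xs] <- wt[ys, xs] + 1
  }
  wt / wt
}
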