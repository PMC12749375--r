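# ------------------------------------------------------------------------
# Self-supervised training-pair construction: parity splitting of EPI
# sub-stacks, the eight orthogonal 2-of-4 masks, dihedral augmentation, and
# training-set assembly. All pairing operations are pure gathers: every
# output pixel is one input pixel, never an interpolation.
# ------------------------------------------------------------------------

#' Split an EPI patch into a noisy input/target sub-stack pair
#'
#' The EPI patch (layout `(outer-spatial, angle, inner-spatial)`) is split
#' along its outer spatial axis by row parity: even-indexed rows form one
#' sub-stack, odd-indexed rows the other. The two sub-stacks image the same
#' structures under independent noise realizations (adjacent rows, same
#' scene), which is what makes them a valid Noise2Noise-style pair;
#' contiguous halves would image different structures and could not serve as
#' such. Which parity acts as the network input is randomized per sample.
#'
#' @param epi 3D array `(S_outer, A, S_inner)` or an `epi_stack`.
#' @param parity `0` (odd-index rows, 1-based rows 1,3,...) or `1`; drawn at
#'   random when `NULL`.
#' @return `list(input, target, parity, orientation)`; `input` and `target`
#'   have half the outer extent and together exhaust the parent.
#' @export
split_substack_pair <- function(epi, parity = NULL) {
  orientation <- if (inherits(epi, "epi_stack")) epi$orientation else NA_character_
  x <- if (inherits(epi, "epi_stack")) epi$data else epi
  d <- dim(x)
  if (d[1] %% 2L != 0L)
    stop(sprintf("split axis length must be even, got %d", d[1]))
  if (is.null(parity)) parity <- sample(0:1, 1L)
  even <- x[seq(1L, d[1], by = 2L), , , drop = FALSE]   # parity grid 0
  odd  <- x[seq(2L, d[1], by = 2L), , , drop = FALSE]   # parity grid 1
  if (parity == 0L) list(input = even, target = odd, parity = 0L,
                         orientation = orientation)
  else list(input = odd, target = even, parity = 1L,
            orientation = orientation)
}

#' @rdname split_substack_pair
#' @param pair a sub-stack pair.
#' @return `recombine_substack_pair`: the parent array, reconstructed
#'   bit-exactly by inverse interleaving.
#' @export
recombine_substack_pair <- function(pair) {
  di <- dim(pair$input)
  out <- array(0, c(2L * di[1], di[2], di[3]))
  if (pair$parity == 0L) {
    out[seq(1L, 2L * di[1], by = 2L), , ] <- pair$input
    out[seq(2L, 2L * di[1], by = 2L), , ] <- pair$target
  } else {
    out[seq(2L, 2L * di[1], by = 2L), , ] <- pair$input
    out[seq(1L, 2L * di[1], by = 2L), , ] <- pair$target
  }
  out
}

#' The eight orthogonal mask patterns
#'
#' Each 2 x 2 spatial cell has four pixels, labeled 1 = (0,0), 2 = (0,1),
#' 3 = (1,0), 4 = (1,1) in (row, column) offsets. The eight patterns are the
#' four edge-adjacent (non-diagonal) pixel pairs in both orderings; diagonal
#' pairs are excluded to keep the two half-resolution sub-images maximally
#' aligned. The table is a documented constant and can be swapped.
#'
#' @return Integer matrix `(8, 2)`; column 1 feeds mask m1, column 2 mask m2.
#' @export
mask_patterns <- function() {
  matrix(c(1L, 2L,
           2L, 1L,
           3L, 4L,
           4L, 3L,
           1L, 3L,
           3L, 1L,
           2L, 4L,
           4L, 2L), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("m1", "m2")))
}

# (row offset, col offset) of cell pixel labels 1..4
.cell_offsets <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), ncol = 2L,
                        byrow = TRUE, dimnames = list(NULL, c("dy", "dx")))

#' Draw an orthogonal mask pair
#'
#' For every 2 x 2 spatial cell, one of the [mask_patterns()] is drawn
#' independently (dense randomness, re-drawn each training iteration); the
#' two derived index maps select two distinct pixels per cell, identically
#' across all angular views, producing half-resolution sub-images.
#'
#' @param spatial_shape integer `(H, W)`, both even.
#' @return `list(pattern_grid, m1, m2)` where `m1`/`m2` are `(H/2 * W/2)`
#'   integer vectors of linear pixel indices into an `(H, W)` plane.
#' @export
sample_mask_pair <- function(spatial_shape) {
  H <- spatial_shape[1]; W <- spatial_shape[2]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("mask sampling requires even spatial dimensions")
  h2 <- H %/% 2L; w2 <- W %/% 2L
  pat <- matrix(sample.int(8L, h2 * w2, replace = TRUE), h2, w2)
  pt <- mask_patterns()
  base_r <- 2L * (row(pat) - 1L) + 1L
  base_c <- 2L * (col(pat) - 1L) + 1L
  lin <- function(lab) {
    r <- base_r + .cell_offsets[lab, 1L]
    c <- base_c + .cell_offsets[lab, 2L]
    as.vector(r + H * (c - 1L))
  }
  list(pattern_grid = pat,
       m1 = lin(pt[pat, 1L]),
       m2 = lin(pt[pat, 2L]))
}

#' Apply a mask index map to a patch
#'
#' Pure gather: the same pixel is picked from every angular view, yielding a
#' patch with half the parent height and width.
#'
#' @param patch 3D array `(A, H, W)`.
#' @param index_map linear pixel indices from [sample_mask_pair()] (`m1` or
#'   `m2`).
#' @return 3D array `(A, H/2, W/2)`.
#' @export
apply_mask <- function(patch, index_map) {
  d <- dim(patch)
  if (length(index_map) != d[2] * d[3] / 4L)
    stop("index map size does not match patch spatial shape")
  m <- matrix(patch, d[1])
  out <- m[, index_map, drop = FALSE]
  dim(out) <- c(d[1], d[2] %/% 2L, d[3] %/% 2L)
  out
}

#' Joint spatial-angular dihedral augmentation
#'
#' Applies one of the eight dihedral-group elements (flips and 90-degree
#' rotations) to a 4D `(U, V, H, W)` patch. Spatial and angular axes are
#' transformed together -- mirroring the image in x also mirrors the
#' horizontal angular coordinate, and transposition swaps both spatial and
#' angular axes -- so EPI slopes remain physically consistent with a
#' transformed scene.
#'
#' @param patch 4D array `(U, V, H, W)`.
#' @param code integer 0..7: bit 1 = horizontal flip, bit 2 = vertical flip,
#'   bit 4 = transpose; drawn at random when `NULL`. Transposition requires
#'   square angular and spatial extents.
#' @return The transformed patch (same dimensions).
#' @export
lf_augment <- function(patch, code = NULL) {
  d <- dim(patch)
  if (is.null(code)) {
    can_t <- d[1] == d[2] && d[3] == d[4]
    code <- sample.int(if (can_t) 8L else 4L, 1L) - 1L
  }
  stopifnot(code %in% 0:7)
  if (bitwAnd(code, 1L) > 0L)   # horizontal: flip x and u
    patch <- patch[rev(seq_len(d[1])), , , rev(seq_len(d[4])), drop = FALSE]
  if (bitwAnd(code, 2L) > 0L)   # vertical: flip y and v
    patch <- patch[, rev(seq_len(d[2])), rev(seq_len(d[3])), , drop = FALSE]
  if (bitwAnd(code, 4L) > 0L) { # transpose: swap (y, x) and (u, v)
    if (d[1] != d[2] || d[3] != d[4])
      stop("transposition requires square angular and spatial extents")
    patch <- aperm(patch, c(2L, 1L, 4L, 3L))
  }
  patch
}

#' Assemble a self-supervised training set
#'
#' Draws `n_patches` spatial patch positions (with augmentation codes and
#' input/target parity assignments) from one or more light fields. Samples
#' are stored as a manifest of origins -- patches, EPI sub-stacks and masks
#' are materialized lazily at training time, and masks are re-drawn every
#' iteration. Each source light field must have more than 8 views.
#'
#' @param lfs list of `lightfield` objects (views already selected/padded).
#' @param n_patches number of patch samples (the standard protocol uses
#'   1000).
#' @param patch_size even spatial patch side.
#' @param seed RNG seed; the manifest is reproducible given the seed.
#' @param scheme angular traversal scheme passed to [lf_to_epi_stack()].
#' @return An object of class `lf_training_set`.
#' @export
build_training_set <- function(lfs, n_patches = 1000L, patch_size = 128L,
                               seed = 1L, scheme = "serpentine") {
  if (length(lfs) == 0L) stop("`lfs` must contain at least one light field")
  stopifnot(patch_size %% 2L == 0L)
  for (lf in lfs) {
    stopifnot(inherits(lf, "lightfield"))
    if (n_views(lf) <= 8L)
      stop("network operations require more than 8 angular views")
    if (any(spatial_shape(lf) < patch_size))
      stop("light field smaller than the patch size; reduce `patch_size`")
  }
  set.seed(seed)
  scales <- vapply(lfs, function(lf) max(lf$data), numeric(1))
  scales[scales <= 0] <- 1
  idx <- sample.int(length(lfs), n_patches, replace = TRUE)
  samples <- data.frame(
    lf = idx,
    y0 = integer(n_patches), x0 = integer(n_patches),
    aug = integer(n_patches), parity = sample(0:1, n_patches, replace = TRUE))
  for (i in seq_len(n_patches)) {
    sp <- spatial_shape(lfs[[idx[i]]])
    d <- dim(lfs[[idx[i]]]$data)
    can_t <- d[1] == d[2]
    samples$y0[i] <- sample.int(sp[1] - patch_size + 1L, 1L)
    samples$x0[i] <- sample.int(sp[2] - patch_size + 1L, 1L)
    samples$aug[i] <- sample.int(if (can_t) 8L else 4L, 1L) - 1L
  }
  structure(list(lfs = lfs, samples = samples, patch_size = patch_size,
                 seed = seed, scheme = scheme, scales = scales),
            class = "lf_training_set")
}

#' @export
print.lf_training_set <- function(x, ...) {
  cat(sprintf("<lf_training_set: %d samples of %d x %d px from %d light field(s)>\n",
              nrow(x$samples), x$patch_size, x$patch_size, length(x$lfs)))
  invisible(x)
}

#' @rdname build_training_set
#' @param tset an `lf_training_set`.
#' @param i sample index.
#' @return `get_training_sample`: `list(patch, parity, scale)` where `patch`
#'   is the augmented, intensity-normalized 4D `(U, V, ps, ps)` array.
#' @export
get_training_sample <- function(tset, i) {
  s <- tset$samples[i, ]
  lf <- tset$lfs[[s$lf]]
  ps <- tset$patch_size
  patch <- lf$data[, , s$y0 + seq_len(ps) - 1L, s$x0 + seq_len(ps) - 1L,
                   drop = FALSE]
  patch <- lf_augment(patch, s$aug)
  list(patch = patch / tset$scales[s$lf], parity = s$parity, scale = tset$scales[s$lf])
}
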