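# ------------------------------------------------------------------------
# End-to-end denoising of a light field with a trained model set.
# ------------------------------------------------------------------------

# Inverse of serialize_patch_angular: (A, H, W) in x-s traversal order back
# to the 4D (U, V, H, W) angular grid.
deserialize_patch_angular <- function(arr, angular_shape, scheme = "serpentine") {
  U <- angular_shape[1]; V <- angular_shape[2]
  d <- dim(arr)
  stopifnot(d[1] == U * V)
  trav <- angular_traversal(U, V, "x-s", scheme)
  flat <- trav[, 1] + U * (trav[, 2] - 1L)
  out <- arr[order(flat), , , drop = FALSE]
  dim(out) <- c(U, V, d[2], d[3])
  out
}

#' Prepare a light field for the network
#'
#' Reduces or pads the angular axis to the model's view count: square grids
#' larger than the required side are centrally cropped
#' ([select_central_views()]); flat layouts with fewer views are padded
#' ([pad_angular_views()]).
#'
#' @param lf a `lightfield`.
#' @param angle_count target flattened view count (must be a square number
#'   for square-grid inputs).
#' @return A `lightfield` with exactly `angle_count` views.
#' @export
prepare_views <- function(lf, angle_count) {
  A <- n_views(lf)
  if (A == angle_count) return(lf)
  d <- dim(lf$data)
  if (d[1] == d[2]) {
    side <- as.integer(round(sqrt(angle_count)))
    if (side * side != angle_count)
      stop(sprintf("cannot reduce a square grid to %d views", angle_count))
    return(select_central_views(lf, side))
  }
  if (d[2] == 1L && A < angle_count) return(pad_angular_views(lf, angle_count))
  stop(sprintf("view count %d not reducible to the supported %d", A, angle_count))
}

#' Denoise a light field
#'
#' Splits the field into overlapping spatial patches, rearranges each patch
#' into both full-size EPI stacks (no sub-stack splitting at inference),
#' passes them through the trained sub-networks, interleaves the outputs
#' and fuses them, then stitches the patches with uniform-average blending.
#' Intensities are normalized by the input maximum on the way in and
#' restored on the way out; outputs are clipped to be non-negative and
#' re-quantized to the input bit depth. Padded angular views are stripped,
#' so output and input have identical shape.
#'
#' @param models a trained `lf_models` set.
#' @param lf input `lightfield`.
#' @param patch_size spatial patch side (default 128).
#' @param overlap patch overlap in pixels (default 16).
#' @param scheme angular traversal scheme (must match training).
#' @param quantize round to integer digital numbers (default TRUE).
#' @param fusion_mode `"parity"` (default) fuses the four half-resolution
#'   parity subgrids independently and reassembles them, so the fusion
#'   module sees inputs with the same spatial statistics it was trained on;
#'   `"full"` feeds the full-resolution patch through the fusion in one
#'   pass. The sub-networks always run on the full, unsplit EPI stacks.
#' @param verbose log shapes and progress.
#' @return A denoised `lightfield` with the same shape and bit depth.
#' @export
denoise_lightfield <- function(models, lf, patch_size = 128L, overlap = 16L,
                               scheme = "serpentine", quantize = TRUE,
                               fusion_mode = c("parity", "full"),
                               verbose = FALSE) {
  fusion_mode <- match.arg(fusion_mode)
  stopifnot(inherits(models, "lf_models"), inherits(lf, "lightfield"))
  A <- models$cfg$angle_count
  lfp <- prepare_views(lf, A)
  d <- dim(lfp$data)
  if (verbose)
    message(sprintf("denoising %d x %d views, %d x %d px (patch %d, overlap %d)",
                    d[1], d[2], d[3], d[4], patch_size, overlap))
  scale <- max(lfp$data)
  if (scale <= 0) return(lf)
  norm <- lightfield(lfp$data / scale, lfp$bit_depth, lfp$system_tag,
                     pad_flags = lfp$pad_flags)
  ex <- extract_patches(norm, patch_size, overlap)
  pa <- yt_to_xs_angular_perm(d[1], d[2], scheme)
  out_patches <- vector("list", length(ex$patches))
  for (i in seq_along(ex$patches)) {
    patch <- ex$patches[[i]]
    plf <- lightfield(patch, lfp$bit_depth, lfp$system_tag)
    yf <- ad_no_grad({
      exs <- lf_to_epi_stack(plf, "x-s", scheme)$data   # (ps, A, ps)
      eyt <- lf_to_epi_stack(plf, "y-t", scheme)$data
      oxs <- ad_value(forward_subnetwork(models$xs, exs))
      oyt <- ad_value(forward_subnetwork(models$yt, eyt))
      y1 <- aperm(oxs, c(2L, 1L, 3L))                   # (A, y, x)
      y2 <- aperm(oyt, c(2L, 3L, 1L))[pa, , , drop = FALSE]
      z <- ad_value(interleave_fusion_input(y1, y2))
      if (fusion_mode == "full") {
        ad_value(forward_fusion(models$fusion, z))
      } else {
        out <- array(0, c(models$cfg$angle_count, patch_size, patch_size))
        for (py in 0:1) for (px in 0:1) {
          iy <- seq(py + 1L, patch_size, by = 2L)
          ix <- seq(px + 1L, patch_size, by = 2L)
          out[, iy, ix] <- ad_value(forward_fusion(
            models$fusion, z[, iy, ix, drop = FALSE]))
        }
        out
      }
    })
    out_patches[[i]] <- deserialize_patch_angular(yf, d[1:2], scheme)
    if (verbose && i %% 10L == 0L)
      message(sprintf("  patch %d / %d", i, length(ex$patches)))
  }
  stitched <- stitch_patches(out_patches, ex$grid, lfp)
  out <- stitched$data * scale
  out <- pmax(out, 0)
  mx <- 2^lfp$bit_depth - 1
  if (quantize) out <- round(pmin(out, mx))
  res <- lightfield(out, lfp$bit_depth, lfp$system_tag, pad_flags = lfp$pad_flags)
  strip_padded_views(res)
}
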