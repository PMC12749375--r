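# ------------------------------------------------------------------------
# Readers/writers: multi-page TIFF light fields (pages angle-major),
# run configuration (YAML), and model checkpoints.
# ------------------------------------------------------------------------

#' Read a light field from a multi-page TIFF
#'
#' Pages are ordered angle-major with the horizontal angular index fastest:
#' page `p` holds the view `(u, v)` with `p = u + U * (v - 1)`. The angular
#' layout comes from a sidecar structured config or the `layout` argument.
#'
#' @param path TIFF file path.
#' @param layout integer `(U, V)` angular layout, or a single view count `A`
#'   (flat layout `(A, 1)`).
#' @param bit_depth,system_tag metadata for the resulting `lightfield`.
#' @param verbose log the shapes read.
#' @return A `lightfield`.
#' @export
read_lightfield <- function(path, layout, bit_depth = 16L,
                            system_tag = "sLFM", verbose = FALSE) {
  if (length(layout) == 1L) layout <- c(layout, 1L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (n != prod(layout))
    stop(sprintf("TIFF has %d pages but layout (%d, %d) needs %d",
                 n, layout[1], layout[2], prod(layout)))
  hw <- dim(pages[[1]])
  out <- array(0, c(layout[1], layout[2], hw[1], hw[2]))
  for (p in seq_len(n)) {
    if (!all(dim(pages[[p]]) == hw))
      stop(sprintf("page %d shape differs from page 1", p))
    u <- ((p - 1L) %% layout[1]) + 1L
    v <- ((p - 1L) %/% layout[1]) + 1L
    out[u, v, , ] <- pages[[p]]
  }
  if (verbose)
    message(sprintf("read %s: %d x %d views, %d x %d px",
                    path, layout[1], layout[2], hw[1], hw[2]))
  lightfield(out, bit_depth, system_tag)
}

#' @rdname read_lightfield
#' @param lf a `lightfield` to write.
#' @export
write_lightfield <- function(lf, path) {
  stopifnot(inherits(lf, "lightfield"))
  d <- dim(lf$data)
  mx <- 2^lf$bit_depth - 1
  pages <- vector("list", d[1] * d[2])
  for (v in seq_len(d[2])) for (u in seq_len(d[1]))
    pages[[u + d[1] * (v - 1L)]] <- pmin(pmax(lf$data[u, v, , ], 0), mx) / mx
  tiff::writeTIFF(pages, path, bits.per.sample = lf$bit_depth,
                  compression = "none")
  invisible(path)
}

#' Run configuration
#'
#' A single structured object that fully specifies a reproducible run:
#' angular layout, network preset, optimizer schedule, camera noise model,
#' projector settings and seeds. Serialized as YAML and echoed into every
#' output directory.
#'
#' @param ... overrides of the default fields.
#' @return A named list of class `lf_run_config`.
#' @export
lf_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    angular = list(U = 13L, V = 13L, side = 9L, system_tag = "sLFM",
                   pad_target = 16L),
    network = list(preset = "standard", angle_count = 81L),
    train = list(n_patches = 1000L, patch_size = 128L, epochs = 25L,
                 lr0 = 1e-4, decay = 0.3, decay_every = 5L),
    noise = list(photon_max = 100, gauss_var = 5, bit_depth = 16L),
    projector = list(n_planes = 16L, kappa = 0.5),
    infer = list(patch_size = 128L, overlap = 16L),
    scheme = "serpentine")
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "lf_run_config"
  cfg
}

#' @rdname lf_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- lf_run_config()
  out <- utils::modifyList(unclass(base), cfg)
  class(out) <- "lf_run_config"
  out
}

#' @rdname lf_run_config
#' @param cfg an `lf_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---- checkpoints ---------------------------------------------------------

params_to_values <- function(x) {
  if (inherits(x, "ad_node")) return(x$v)
  if (is.list(x)) return(lapply(x, params_to_values))
  x
}

values_into_params <- function(x, vals) {
  if (inherits(x, "ad_node")) { x$v <- vals; return(invisible(NULL)) }
  if (is.list(x)) for (nm in seq_along(x)) values_into_params(x[[nm]], vals[[nm]])
  invisible(NULL)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the network configuration, all weight arrays and an
#' optional training manifest, so a run can be resumed or audited.
#'
#' @param models an `lf_models` set.
#' @param path file path (`.rds`).
#' @param manifest optional training manifest (e.g. the sample table of the
#'   training set and the optimizer seed).
#' @export
save_checkpoint <- function(models, path, manifest = NULL) {
  obj <- list(cfg = unclass(models$cfg),
              values = list(xs = params_to_values(models$xs$params),
                            yt = params_to_values(models$yt$params),
                            fusion = params_to_values(models$fusion$params)),
              manifest = manifest)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored `lf_models`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$cfg, class = "lf_network_config")
  models <- build_lf_models(cfg)
  values_into_params(models$xs$params, obj$values$xs)
  values_into_params(models$yt$params, obj$values$yt)
  values_into_params(models$fusion$params, obj$values$fusion)
  models$manifest <- obj$manifest
  models
}
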