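# ------------------------------------------------------------------------
# Synthetic light-field generator: 3D phantoms, a geometric shift-and-sum
# projector standing in for the microscope's phase-space forward model, and
# the Poisson-Gaussian camera noise model used in the simulation studies.
# ------------------------------------------------------------------------

#' Generate a 3D phantom volume
#'
#' Produces reproducible fluorescent test scenes: `"beads"` are isotropic
#' Gaussian blobs (emulating nuclei/vesicles), `"tubes"` are random 3D
#' polylines rendered as chains of small Gaussian splats (emulating
#' microtubules/vessels), `"mixed"` combines both. Intensities are
#' non-negative with maximum 1.
#'
#' @param kind one of `"beads"`, `"tubes"`, `"mixed"`.
#' @param shape integer length-3, volume extent `(Z, Y, X)` (each >= 16).
#' @param n_objects number of beads / tubes (> 0).
#' @param seed RNG seed for reproducibility.
#' @param bead_sigma Gaussian blob standard deviation in voxels.
#' @return 3D array `(Z, Y, X)`, class `volume`.
#' @export
make_phantom <- function(kind = c("beads", "tubes", "mixed"),
                         shape = c(16L, 64L, 64L), n_objects = 10L,
                         seed = 1L, bead_sigma = 1.6) {
  kind <- match.arg(kind)
  stopifnot(length(shape) == 3L)
  if (any(shape < 16L)) stop("each phantom axis must be >= 16 voxels")
  if (n_objects <= 0L) stop("`n_objects` must be positive")
  set.seed(seed)
  vol <- array(0, shape)
  margin <- 4
  rand_center <- function() c(
    stats::runif(1, 1 + margin, shape[1] - margin),
    stats::runif(1, 1 + margin, shape[2] - margin),
    stats::runif(1, 1 + margin, shape[3] - margin))
  centers <- NULL
  if (kind %in% c("beads", "mixed")) {
    nb <- if (kind == "mixed") ceiling(n_objects / 2) else n_objects
    centers <- t(replicate(nb, rand_center()))
    for (i in seq_len(nb))
      vol <- splat_gaussian(vol, centers[i, ], bead_sigma,
                            amp = stats::runif(1, 0.6, 1))
  }
  if (kind %in% c("tubes", "mixed")) {
    nt <- if (kind == "mixed") floor(n_objects / 2) else n_objects
    for (i in seq_len(nt)) {
      p <- rand_center()
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      amp <- stats::runif(1, 0.5, 0.9)
      n_seg <- 40L
      for (s in seq_len(n_seg)) {
        dir <- dir + stats::rnorm(3, sd = 0.15)
        dir <- dir / sqrt(sum(dir^2))
        p <- p + dir * 1.2
        p <- pmin(pmax(p, 1 + margin), shape - margin)
        vol <- splat_gaussian(vol, p, 1.0, amp = amp)
      }
    }
  }
  vol <- vol / max(vol)
  structure(vol, class = c("volume", class(vol)),
            phantom_kind = kind, centers = centers, seed = seed)
}

# Add a Gaussian blob at fractional center `ctr` (z, y, x) within a local
# window of +-4 sigma.
splat_gaussian <- function(vol, ctr, sigma, amp = 1) {
  shape <- dim(vol)
  r <- ceiling(4 * sigma)
  rng <- lapply(1:3, function(a)
    max(1L, floor(ctr[a] - r)):min(shape[a], ceiling(ctr[a] + r)))
  gz <- exp(-((rng[[1]] - ctr[1])^2) / (2 * sigma^2))
  gy <- exp(-((rng[[2]] - ctr[2])^2) / (2 * sigma^2))
  gx <- exp(-((rng[[3]] - ctr[3])^2) / (2 * sigma^2))
  blob <- amp * outer(outer(gz, gy), gx)
  vol[rng[[1]], rng[[2]], rng[[3]]] <-
    vol[rng[[1]], rng[[2]], rng[[3]]] + blob
  vol
}

#' Geometric light-field projector
#'
#' Maps a volume to angular views by shift-and-sum: the view at angular
#' index `(u, v)` is the sum over depth planes of each plane translated by
#' the disparity `d(z) * (v - v0, u - u0)` with bilinear sub-pixel
#' interpolation. The disparity is linear in depth, `d(z) = kappa * (z -
#' z0)`, zero at the native focal plane `z0`, and antisymmetric about the
#' central view. This is a simplified geometric stand-in for the wave-optics
#' phase-space model of the instrument; it preserves the linear structure
#' (shifted copies, slope encodes depth) that the EPI representation and the
#' tomographic reconstruction exploit.
#'
#' @param angular_shape integer `(U, V)` angular grid.
#' @param n_planes number of depth planes covered.
#' @param kappa disparity slope, pixels of shift per depth plane per angular
#'   step.
#' @param z0 focal plane index (default: volume center).
#' @return An object of class `lf_projector`.
#' @export
lf_projector <- function(angular_shape = c(9L, 9L), n_planes = 16L,
                         kappa = 0.5, z0 = (n_planes + 1) / 2) {
  stopifnot(all(angular_shape >= 1L), n_planes >= 1L)
  structure(list(angular_shape = as.integer(angular_shape),
                 n_planes = as.integer(n_planes),
                 kappa = kappa, z0 = z0,
                 u0 = (angular_shape[1] + 1) / 2,
                 v0 = (angular_shape[2] + 1) / 2),
            class = "lf_projector")
}

#' @rdname lf_projector
#' @param proj an `lf_projector`.
#' @param z depth plane index.
#' @export
disparity_at <- function(proj, z) proj$kappa * (z - proj$z0)

# Bilinear translation of a matrix by (dy, dx), zero padding outside.
shift_bilinear <- function(img, dy, dx) {
  d <- dim(img)
  if (abs(dy) >= d[1] || abs(dx) >= d[2]) {
    warning("shift exceeds spatial extent; view filled with zeros")
    return(matrix(0, d[1], d[2]))
  }
  iy <- floor(dy); fx <- dx - floor(dx); fy <- dy - iy; ix <- floor(dx)
  g <- function(sy, sx) {
    # img sampled at (y - sy, x - sx), zero outside
    out <- matrix(0, d[1], d[2])
    ys <- seq_len(d[1]) - sy
    xs <- seq_len(d[2]) - sx
    vy <- ys >= 1L & ys <= d[1]
    vx <- xs >= 1L & xs <= d[2]
    out[vy, vx] <- img[ys[vy], xs[vx], drop = FALSE]
    out
  }
  (1 - fy) * (1 - fx) * g(iy, ix) +
    (1 - fy) * fx * g(iy, ix + 1L) +
    fy * (1 - fx) * g(iy + 1L, ix) +
    fy * fx * g(iy + 1L, ix + 1L)
}

#' Project a volume to a light field
#'
#' @param vol 3D array `(Z, Y, X)`; `Z` must equal the projector's
#'   `n_planes`.
#' @param proj an [lf_projector()].
#' @param bit_depth bit depth tag for the resulting light field.
#' @return A noiseless `lightfield` (intensities not yet quantized).
#' @export
project_volume <- function(vol, proj, bit_depth = 16L) {
  d <- dim(vol)
  if (d[1] != proj$n_planes)
    stop(sprintf("projector covers %d planes but volume has %d",
                 proj$n_planes, d[1]))
  U <- proj$angular_shape[1]; V <- proj$angular_shape[2]
  out <- array(0, c(U, V, d[2], d[3]))
  for (u in seq_len(U)) for (v in seq_len(V)) {
    acc <- matrix(0, d[2], d[3])
    for (z in seq_len(d[1])) {
      dz <- disparity_at(proj, z)
      if (dz == 0) {
        acc <- acc + vol[z, , ]
      } else {
        acc <- acc + shift_bilinear(vol[z, , ],
                                    dz * (v - proj$v0), dz * (u - proj$u0))
      }
    }
    out[u, v, , ] <- acc
  }
  lightfield(out, bit_depth = bit_depth, system_tag = "sLFM")
}

#' Camera noise parameters
#'
#' @param photon_max expected photon count at the brightest pixel (the
#'   simulation studies use 100 for the low-light condition).
#' @param gauss_sigma standard deviation of additive Gaussian read noise in
#'   digital numbers; `gauss_var` may be given instead (the low-light
#'   condition uses variance 5).
#' @param bit_depth 8 or 16.
#' @param seed RNG seed.
#' @param gauss_var convenience: Gaussian variance, converted to sigma.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(photon_max = 100, gauss_sigma = NULL,
                         bit_depth = 16L, seed = 1L, gauss_var = NULL) {
  if (is.null(gauss_sigma)) {
    gauss_sigma <- if (is.null(gauss_var)) sqrt(5) else sqrt(gauss_var)
  }
  if (photon_max <= 0) stop("`photon_max` must be positive")
  if (gauss_sigma < 0) stop("`gauss_sigma` must be non-negative")
  stopifnot(bit_depth %in% c(8L, 16L))
  structure(list(photon_max = photon_max, gauss_sigma = gauss_sigma,
                 bit_depth = as.integer(bit_depth), seed = seed),
            class = "noise_params")
}

#' Apply the Poisson-Gaussian camera model
#'
#' The clean light field is scaled so its maximum expected intensity equals
#' `photon_max` photons; each pixel is then Poisson-sampled (shot noise,
#' camera gain fixed at 1 digital number per photon), Gaussian read noise of
#' standard deviation `gauss_sigma` is added, and the result is clipped to
#' the bit-depth range and rounded to integers.
#'
#' @param clean a non-negative `lightfield` (any scale).
#' @param np a [noise_params()].
#' @return `list(noisy = <lightfield>, clean_scaled = <lightfield>)` where
#'   `clean_scaled` is the noiseless image on the photon scale (the ground
#'   truth against which denoising is scored).
#' @export
corrupt <- function(clean, np = noise_params()) {
  stopifnot(inherits(clean, "lightfield"))
  if (any(clean$data < 0)) stop("clean light field must be non-negative")
  set.seed(np$seed)
  mx <- max(clean$data)
  if (mx <= 0) stop("clean light field is identically zero")
  scaled <- clean$data * (np$photon_max / mx)
  n <- length(scaled)
  noisy <- stats::rpois(n, lambda = as.vector(scaled))
  if (np$gauss_sigma > 0)
    noisy <- noisy + stats::rnorm(n, sd = np$gauss_sigma)
  noisy <- round(pmin(pmax(noisy, 0), 2^np$bit_depth - 1))
  dim(noisy) <- dim(scaled)
  list(noisy = lightfield(noisy, np$bit_depth, clean$system_tag,
                          pad_flags = clean$pad_flags),
       clean_scaled = lightfield(scaled, np$bit_depth, clean$system_tag,
                                 pad_flags = clean$pad_flags))
}

#' Simulate a noisy light-field acquisition end to end
#'
#' Convenience wrapper: phantom -> geometric projection -> Poisson-Gaussian
#' camera. Used by the training-set builder, the command-line `simulate`
#' subcommand and the test fixtures.
#'
#' @inheritParams make_phantom
#' @param proj an [lf_projector()]; its `n_planes` must match `shape[1]`.
#' @param np a [noise_params()].
#' @return `list(noisy, clean_scaled, volume, projector)`.
#' @export
simulate_lightfield <- function(kind = "beads", shape = c(16L, 64L, 64L),
                                n_objects = 10L, seed = 1L,
                                proj = lf_projector(n_planes = shape[1]),
                                np = noise_params(seed = seed + 1L)) {
  vol <- make_phantom(kind, shape, n_objects, seed)
  clean <- project_volume(vol, proj, bit_depth = np$bit_depth)
  out <- corrupt(clean, np)
  out$volume <- vol
  out$projector <- proj
  out
}
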