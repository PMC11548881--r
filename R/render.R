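# Forward optics model: membranes are 1D curves carrying line densities
# (photons per um), cytosol/lumen are area sources (photons per um^2). The
# scene is rasterized at the pixel pitch, convolved with an isotropic
# Gaussian PSF, scaled by photon_scale, and (for the noisy image) subjected
# to Poisson shot noise plus Gaussian read noise.
#
# All channels share the *same* geometry rasters, scaled per channel, so the
# noiseless protein and reference planes of a single-structure scene are
# proportional pixel-for-pixel. That shared geometry is what makes the
# density-ratio estimator independent of vesicle size and PSF width.

# deposit a circle (centre um, radius um, unit line density) on an H x W
# grid by bilinear splatting of finely spaced arc samples, so the rasterized
# line measure is smooth to well below the PSF scale
circle_deposit <- function(center, radius, pixel_size, H, W, step_frac = 0.25) {
  ds <- pixel_size * step_frac
  np <- max(8L, ceiling(2 * pi * radius / ds))
  th <- (seq_len(np) - 0.5) / np * 2 * pi
  x <- center[1] + radius * cos(th)
  y <- center[2] + radius * sin(th)
  # pixel centre (i, j) sits at ((j - 0.5) px, (i - 0.5) px)
  fj <- x / pixel_size + 0.5
  fi <- y / pixel_size + 0.5
  j0 <- pmin(pmax(floor(fj), 1), W); i0 <- pmin(pmax(floor(fi), 1), H)
  j1 <- pmin(j0 + 1, W); i1 <- pmin(i0 + 1, H)
  tx <- pmin(pmax(fj - j0, 0), 1); ty <- pmin(pmax(fi - i0, 0), 1)
  w0 <- 2 * pi * radius / np
  idx <- c((j0 - 1) * H + i0, (j1 - 1) * H + i0,
           (j0 - 1) * H + i1, (j1 - 1) * H + i1)
  w <- w0 * c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  acc <- rowsum(w, idx)
  list(idx = as.integer(rownames(acc)), w = as.numeric(acc))
}

# pixel-centre coordinate grids (um)
pixel_grid <- function(H, W, pixel_size) {
  list(x = ((seq_len(W)) - 0.5) * pixel_size,
       y = ((seq_len(H)) - 0.5) * pixel_size)
}

disc_mask <- function(center, radius, pixel_size, H, W) {
  g <- pixel_grid(H, W, pixel_size)
  dx2 <- (g$x - center[1])^2
  dy2 <- (g$y - center[2])^2
  outer(dy2, dx2, "+") <= radius^2
}

#' Render the noiseless intensity field of a scene
#'
#' Rasterizes the membrane line sources and cytosol/lumen area sources of a
#' `cell_scene` at the configured pixel pitch, convolves each channel with
#' the Gaussian PSF, and scales by `photon_scale`. No noise is added and no
#' clipping is applied.
#'
#' The cytosolic level fills the cell interior (nucleus excluded) uniformly,
#' including across vesicle footprints: in a single confocal section the
#' cytosol above and below a sub-micrometre vesicle still contributes, so a
#' vesicle does not punch a hole in the background. Vesicle `lumen_level`
#' adds on top of that within the vesicle disc.
#'
#' @param scene a `cell_scene`.
#' @param config an `imaging_config`; only roles present in the scene's
#'   density vectors are rendered.
#' @return numeric array `H x W x C` of expected photon counts, with
#'   `dimnames[[3]]` the channel roles.
#' @export
render_field <- function(scene, config = imaging_config()) {
  stopifnot(inherits(scene, "cell_scene"), inherits(config, "imaging_config"))
  px <- config$pixel_size
  H <- W <- as.integer(round(scene$image_size_um / px))
  roles <- names(sort(config$channel_roles))
  missing <- setdiff(roles, names(scene$pm_density))
  if (length(missing))
    stop("scene lacks densities for channel role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  pm_dep <- circle_deposit(scene$center, scene$cell_radius, px, H, W)
  ves_dep <- lapply(scene$vesicles, function(v)
    circle_deposit(v$center, v$radius, px, H, W))
  cyt_mask <- disc_mask(scene$center, scene$cell_radius, px, H, W) &
    !disc_mask(scene$center, scene$nucleus_radius, px, H, W)
  lum_masks <- NULL

  field <- array(0, dim = c(H, W, length(roles)),
                 dimnames = list(NULL, NULL, roles))
  sigma_px <- config$psf_sigma / px
  for (k in seq_along(roles)) {
    role <- roles[k]
    plane <- matrix(0, H, W)
    plane[pm_dep$idx] <- plane[pm_dep$idx] + scene$pm_density[[role]] * pm_dep$w
    for (vi in seq_along(scene$vesicles)) {
      v <- scene$vesicles[[vi]]
      d <- v$rho[[role]] * scene$pm_density[[role]]
      if (d > 0) {
        dep <- ves_dep[[vi]]
        plane[dep$idx] <- plane[dep$idx] + d * dep$w
      }
      if (v$lumen_level[[role]] > 0) {
        if (is.null(lum_masks)) lum_masks <- vector("list", length(scene$vesicles))
        if (is.null(lum_masks[[vi]]))
          lum_masks[[vi]] <- disc_mask(v$center, v$radius, px, H, W)
        plane[lum_masks[[vi]]] <- plane[lum_masks[[vi]]] +
          v$lumen_level[[role]] * px^2
      }
    }
    if (scene$cytosol_level[[role]] > 0)
      plane[cyt_mask] <- plane[cyt_mask] + scene$cytosol_level[[role]] * px^2
    if (sigma_px > 0) {
      plane <- EBImage::gblur(plane, sigma = sigma_px)
      # FFT convolution can leave O(1e-12) negative ripple; the field is a
      # photon rate and must be non-negative
      plane[plane < 0] <- 0
    }
    field[, , k] <- plane * config$photon_scale
  }
  field
}

#' Render a noisy multi-channel image of a scene
#'
#' Applies the detector model to the noiseless field of [render_field()]:
#' per-pixel Poisson shot noise on the expected photon count, additive
#' Gaussian read noise, rounding, and clipping to the detector bit depth.
#' Bit-identical across runs for a fixed `(scene, config, seed)`.
#'
#' @inheritParams render_field
#' @param seed integer seed for the noise draw.
#' @return An object of class `mc_image`: list with `pixels` (integer array
#'   `H x W x C`), `pixel_size`, `channel_roles`, `bit_depth`, the generating
#'   `scene`, `config` and `seed`.
#' @export
render_image <- function(scene, config = imaging_config(), seed = 1L) {
  field <- render_field(scene, config)
  set.seed(as.integer(seed))
  n <- length(field)
  counts <- rpois(n, lambda = as.numeric(field))
  if (config$read_noise_sd > 0)
    counts <- counts + rnorm(n, 0, config$read_noise_sd)
  maxval <- 2^config$bit_depth - 1
  pixels <- array(pmin(pmax(round(counts), 0), maxval), dim = dim(field),
                  dimnames = dimnames(field))
  structure(list(pixels = pixels,
                 pixel_size = config$pixel_size,
                 channel_roles = config$channel_roles,
                 bit_depth = config$bit_depth,
                 scene = scene,
                 config = config,
                 seed = as.integer(seed)),
            class = "mc_image")
}

#' Wrap a pixel array as an `mc_image`
#'
#' Lower-level constructor used when reading images from disk or building
#' test fixtures directly from arrays.
#'
#' @param pixels numeric array `H x W x C`.
#' @param pixel_size um per pixel.
#' @param channel_roles named integer vector role -> plane index.
#' @param bit_depth detector bit depth.
#' @param scene optional generating `cell_scene` (ground truth).
#' @return An `mc_image`.
#' @export
mc_image <- function(pixels, pixel_size, channel_roles, bit_depth = 16L,
                     scene = NULL) {
  if (length(dim(pixels)) == 2L) pixels <- array(pixels, c(dim(pixels), 1L))
  if (dim(pixels)[3] != length(channel_roles))
    stop("channel count does not match declared roles", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1)
    stop("pixel values outside bit-depth range", call. = FALSE)
  dimnames(pixels) <- list(NULL, NULL, names(channel_roles)[order(channel_roles)])
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel_roles = channel_roles, bit_depth = as.integer(bit_depth),
                 scene = scene, config = NULL, seed = NULL),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mc_image> %d x %d px (%.2f um/px), channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channel_roles), collapse = ", ")))
  invisible(x)
}

# resolve a channel role or index to a plane index
channel_index <- function(image, channel) {
  if (is.character(channel)) {
    if (!channel %in% names(image$channel_roles))
      stop("unknown channel role: ", channel, call. = FALSE)
    unname(image$channel_roles[[channel]])
  } else as.integer(channel)
}
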