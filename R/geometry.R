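#' Imaging configuration for the synthetic confocal generator
#'
#' Collects the optical and detector parameters of the forward model. The
#' defaults describe a plausible 63x/1.40 NA point-scanning confocal at
#' Nyquist-ish sampling; they are assumptions of the simulator, not measured
#' values.
#'
#' @param pixel_size pixel pitch in micrometres per pixel.
#' @param psf_sigma standard deviation of the isotropic Gaussian point-spread
#'   function, in micrometres. `0` disables blurring.
#' @param photon_scale expected detected photons per unit of scene photon
#'   rate; a global gain applied before shot noise.
#' @param read_noise_sd standard deviation of the additive Gaussian read
#'   noise, in counts.
#' @param bit_depth detector bit depth; one of 8 or 16.
#' @param channel_roles named integer vector mapping channel roles (e.g.
#'   `protein`, `reference_dye`, `receptor`, `marker`) to plane indices.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 0.1,
                           psf_sigma = 0.15,
                           photon_scale = 1,
                           read_noise_sd = 2,
                           bit_depth = 16L,
                           channel_roles = c(protein = 1L, reference_dye = 2L)) {
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("invalid imaging parameter 'pixel_size': must be > 0", call. = FALSE)
  if (!is.numeric(psf_sigma) || psf_sigma < 0)
    stop("invalid imaging parameter 'psf_sigma': must be >= 0", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("invalid imaging parameter 'bit_depth': must be 8 or 16", call. = FALSE)
  if (is.null(names(channel_roles)) || any(!nzchar(names(channel_roles))))
    stop("invalid imaging parameter 'channel_roles': must be a named vector",
         call. = FALSE)
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 channel_roles = vapply(channel_roles, as.integer, integer(1))),
            class = "imaging_config")
}

# Default photon-rate levels per channel role, chosen once to give realistic
# 16-bit count levels (PM peak ~2500 counts for the protein channel at the
# default optics, ~4000 for the bright reference dye; dim cytosol for the
# protein, near-dark cytosol for the membrane-partitioned dye).
default_pm_density <- c(protein = 94000, reference_dye = 150000,
                        receptor = 120000, marker = 100000)
default_cytosol_level <- c(protein = 8000, reference_dye = 2500,
                           receptor = 3000, marker = 2000)

#' Build the ground-truth geometry of a simulated cell
#'
#' Creates a `cell_scene`: a circular plasma-membrane contour enclosing a
#' circular nucleus, with per-channel PM line densities (photons per um of
#' membrane) and cytosolic levels (photons per um^2). Vesicles are added
#' separately with [place_vesicles()].
#'
#' @param image_size_um side length of the (square) field of view, um.
#' @param cell_radius,nucleus_radius radii in um; the cell must be larger
#'   than the nucleus and fit in the field of view.
#' @param center cell centre in um; default is the image centre.
#' @param pm_density named numeric vector of PM line densities per channel
#'   role (photon rate per um of membrane).
#' @param cytosol_level named numeric vector of cytosolic area levels per
#'   channel role (photon rate per um^2). The nucleus is excluded.
#' @param seed integer seed recorded in the scene (the default circular
#'   geometry is deterministic; the seed seeds vesicle placement downstream).
#' @return An object of class `cell_scene`.
#' @export
build_cell_geometry <- function(image_size_um = 20,
                                cell_radius = 7.5,
                                nucleus_radius = 3.5,
                                center = NULL,
                                pm_density = default_pm_density[c("protein", "reference_dye")],
                                cytosol_level = default_cytosol_level[c("protein", "reference_dye")],
                                seed = 1L) {
  if (!is.numeric(cell_radius) || cell_radius <= 0)
    stop("invalid geometry parameter 'cell_radius': must be > 0", call. = FALSE)
  if (!is.numeric(nucleus_radius) || nucleus_radius < 0)
    stop("invalid geometry parameter 'nucleus_radius': must be >= 0", call. = FALSE)
  if (nucleus_radius >= cell_radius)
    stop("invalid geometry parameter 'nucleus_radius': must be smaller than 'cell_radius'",
         call. = FALSE)
  if (is.null(center)) center <- c(image_size_um / 2, image_size_um / 2)
  if (cell_radius > min(center, image_size_um - center))
    stop("invalid geometry parameter 'cell_radius': cell does not fit in the field of view",
         call. = FALSE)
  if (any(pm_density < 0) || any(cytosol_level < 0))
    stop("invalid geometry parameter: densities and levels must be >= 0", call. = FALSE)
  roles <- union(names(pm_density), names(cytosol_level))
  pm <- structure(rep(0, length(roles)), names = roles)
  cy <- pm
  pm[names(pm_density)] <- pm_density
  cy[names(cytosol_level)] <- cytosol_level
  theta <- seq(0, 2 * pi, length.out = 361L)[-361L]
  contour <- cbind(x = center[1] + cell_radius * cos(theta),
                   y = center[2] + cell_radius * sin(theta))
  structure(list(image_size_um = image_size_um,
                 center = center,
                 cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius,
                 pm_contour = contour,
                 pm_density = pm,
                 cytosol_level = cy,
                 vesicles = list(),
                 seed = as.integer(seed)),
            class = "cell_scene")
}

#' Moment-matched zero-clipped normal
#'
#' Finds `(mu, sigma)` of a latent normal such that `max(0, N(mu, sigma))`
#' has the requested mean and standard deviation, and draws from it. The
#' atom at zero models structures carrying no detectable protein.
#'
#' @param mean,sd target mean and standard deviation of the clipped draw.
#' @return `clipnorm_params` returns `c(mu, sigma)`; `rclipnorm` returns
#'   `n` draws.
#' @export
clipnorm_params <- function(mean, sd) {
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  moments <- function(mu, sigma) {
    a <- mu / sigma
    m1 <- mu * pnorm(a) + sigma * dnorm(a)
    m2 <- (mu^2 + sigma^2) * pnorm(a) + mu * sigma * dnorm(a)
    c(m1, sqrt(pmax(m2 - m1^2, 0)))
  }
  obj <- function(par) {
    m <- moments(par[1], exp(par[2]))
    (m[1] - mean)^2 + (m[2] - sd)^2
  }
  fit <- optim(c(mean - sd / 2, log(sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  m <- moments(out[1], out[2])
  if (max(abs(m - c(mean, sd))) > 1e-4 * max(1, mean, sd))
    stop("clipnorm_params: moment matching failed to converge", call. = FALSE)
  out
}

#' @rdname clipnorm_params
#' @param n number of draws.
#' @export
rclipnorm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  par <- clipnorm_params(mean, sd)
  pmax(0, rnorm(n, par[1], par[2]))
}

# sample one membrane-density fraction per channel for one vesicle
sample_rho <- function(rho_spec) {
  vapply(rho_spec, function(r) {
    if (is.list(r)) {
      if (is.null(r$sd) || r$sd == 0) r$mean else pmax(0, rnorm(1, attr(r, "mu"), attr(r, "sigma")))
    } else as.numeric(r)
  }, numeric(1))
}

#' Place vesicles in the cytosol of a scene
#'
#' Adds non-overlapping circular vesicles (equatorial sections of endocytic
#' vesicles) to a `cell_scene`, away from the plasma membrane and the
#' nucleus, and records their per-channel ground-truth membrane density as a
#' fraction `rho` of the PM density in the same channel. `rho` may be a fixed
#' number per channel, or `list(mean=, sd=)` to draw one value per vesicle
#' from a zero-clipped normal (vesicle-to-vesicle heterogeneity; the atom at
#' zero represents vesicles with no detectable protein).
#'
#' @param scene a `cell_scene`.
#' @param n number of vesicles to add.
#' @param rho named list over channel roles: each element a number or
#'   `list(mean=, sd=)`. The reference-dye channel defaults to 1 (the dye
#'   reports membrane surface area at PM-equal density).
#' @param radius_range vesicle radius range in um, drawn uniformly.
#' @param kind_label one of `"constitutive"`, `"receptor_positive"`,
#'   `"lysosome"`.
#' @param lumen_level named numeric per-channel photon rate per um^2 inside
#'   the vesicle (default 0: the reference dye is membrane-partitioned).
#' @param pm_margin minimum distance from a vesicle centre to the PM contour,
#'   um; the effective margin is `max(pm_margin, 2 * diameter)`.
#' @param nucleus_margin minimum distance from a vesicle edge to the nucleus.
#' @param min_gap minimum edge-to-edge separation between vesicles, um.
#' @param retry_budget placement attempts per vesicle before giving up.
#' @param seed integer seed; placement and density draws are deterministic
#'   for a fixed seed.
#' @return The scene with `n` additional vesicles.
#' @export
place_vesicles <- function(scene, n,
                           rho = list(protein = list(mean = 0.2, sd = 0),
                                      reference_dye = 1.0),
                           radius_range = c(0.25, 0.6),
                           kind_label = "constitutive",
                           lumen_level = NULL,
                           pm_margin = 2.0,
                           nucleus_margin = 1.0,
                           min_gap = 0.3,
                           retry_budget = 200L,
                           seed = 1L) {
  stopifnot(inherits(scene, "cell_scene"))
  if (n == 0) return(scene)
  roles <- names(scene$pm_density)
  if (!"reference_dye" %in% names(rho) && "reference_dye" %in% roles)
    rho$reference_dye <- 1.0
  for (nm in names(rho)) {
    r <- rho[[nm]]
    if (is.list(r)) {
      if (r$mean < 0 || is.null(r$sd) || r$sd < 0)
        stop("invalid vesicle parameter 'rho': mean and sd must be >= 0", call. = FALSE)
      if (r$sd > 0) {
        par <- clipnorm_params(r$mean, r$sd)
        attr(r, "mu") <- par[[1]]; attr(r, "sigma") <- par[[2]]
        rho[[nm]] <- r
      }
    } else if (r < 0) stop("invalid vesicle parameter 'rho': must be >= 0", call. = FALSE)
  }
  if (any(radius_range <= 0) || radius_range[1] > radius_range[2])
    stop("invalid vesicle parameter 'radius_range'", call. = FALSE)
  set.seed(as.integer(seed))
  ves <- scene$vesicles
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(retry_budget)) {
      r <- runif(1, radius_range[1], radius_range[2])
      lo <- scene$nucleus_radius + nucleus_margin + r
      hi <- scene$cell_radius - max(pm_margin, 2 * r)
      if (lo >= hi) next
      rad <- sqrt(runif(1, lo^2, hi^2))
      th <- runif(1, 0, 2 * pi)
      ctr <- scene$center + rad * c(cos(th), sin(th))
      ok <- TRUE
      for (v in ves) {
        if (sqrt(sum((ctr - v$center)^2)) < r + v$radius + min_gap) { ok <- FALSE; break }
      }
      if (ok) {
        dens <- structure(rep(0, length(roles)), names = roles)
        drawn <- sample_rho(rho)
        dens[names(drawn)] <- drawn
        lum <- structure(rep(0, length(roles)), names = roles)
        if (!is.null(lumen_level)) lum[names(lumen_level)] <- lumen_level
        ves[[length(ves) + 1L]] <- list(center = ctr, radius = r,
                                        rho = dens, lumen_level = lum,
                                        kind_label = kind_label)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("vesicle placement failed after %d retries: placed %d of %d",
                   retry_budget, length(ves) - length(scene$vesicles), n),
           call. = FALSE)
  }
  scene$vesicles <- ves
  scene
}

#' @export
print.cell_scene <- function(x, ...) {
  cat(sprintf("<cell_scene> %g um field, cell r=%g um, nucleus r=%g um, %d vesicle(s)\n",
              x$image_size_um, x$cell_radius, x$nucleus_radius, length(x$vesicles)))
  cat("  channels:", paste(names(x$pm_density), collapse = ", "), "\n")
  invisible(x)
}
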