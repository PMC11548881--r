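# Fixture builders shared across test files. All fixtures are generated in
# code; "noiseless" images wrap the expected-photon field directly so that
# estimator properties can be checked to numerical precision.

# a noiseless single-vesicle image with zero cytosol (pure membrane geometry)
noiseless_vesicle_image <- function(rho_protein = 0.64, radius = 0.4,
                                    psf_sigma = 0.15, rho_receptor = NULL,
                                    cytosol = c(protein = 0, reference_dye = 0),
                                    seed = 11L) {
  roles <- c(protein = 1L, reference_dye = 2L)
  rho <- list(protein = rho_protein, reference_dye = 1.0)
  pm <- c(protein = 94000, reference_dye = 150000)
  if (!is.null(rho_receptor)) {
    roles <- c(roles, receptor = 3L)
    rho$receptor <- rho_receptor
    pm <- c(pm, receptor = 120000)
    cytosol <- c(cytosol, receptor = 0)
  }
  sc <- build_cell_geometry(pm_density = pm, cytosol_level = cytosol)
  sc <- place_vesicles(sc, 1, rho = rho, radius_range = c(radius, radius),
                       seed = seed)
  ic <- imaging_config(psf_sigma = psf_sigma, read_noise_sd = 0,
                       channel_roles = roles)
  f <- render_field(sc, ic)
  img <- mc_image(f, pixel_size = ic$pixel_size, channel_roles = roles,
                  scene = sc)
  img$config <- ic
  img
}

# analytic PSF-blurred circle: expected per-pixel intensity at distance
# `dist` from the centre of a circle of radius r carrying line density d
# (photons/um), for Gaussian PSF sigma and pixel size px. Independent
# closed-form oracle for the raster + FFT renderer.
#
# The renderer splats arc samples bilinearly (triangle kernel, variance
# px^2/6) and profiles read the raster by bilinear interpolation (another
# px^2/6), so raster measurements correspond to an effective Gaussian width
# slightly above the optical sigma:
effective_sigma <- function(sigma, px) sqrt(sigma^2 + px^2 / 3)

analytic_circle_intensity <- function(dist, r, d, sigma, px) {
  x <- r * dist / sigma^2
  d * px^2 * (r / sigma^2) *
    exp(x - (dist^2 + r^2) / (2 * sigma^2)) *
    besselI(x, 0, expon.scaled = TRUE)
}

# brute-force two-stage BKY step-up, written independently of the package
# implementation (plain loops over the sorted p-values)
brute_bky <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  bh_k <- function(level) {
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= level * i / m) k <- i
    k
  }
  q1 <- q / (1 + q)
  r1 <- bh_k(q1)
  k <- if (r1 == 0 || r1 == m) r1 else bh_k(q1 * m / (m - r1))
  rej <- logical(m)
  if (k > 0) rej[o[1:k]] <- TRUE
  rej
}
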