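# Measurement layer: line profiles across vesicles and the plasma membrane,
# PM reference values, ROI means and signal/background ratios. Mirrors an
# ImageJ-style workflow: 3 um lines centred on structures, a nearby
# PM-crossing line for normalization, and a nearby cytosol ROI for
# background.

bilinear_sample <- function(plane, x_um, y_um, pixel_size) {
  H <- nrow(plane); W <- ncol(plane)
  fx <- x_um / pixel_size + 0.5
  fy <- y_um / pixel_size + 0.5
  j0 <- floor(fx); i0 <- floor(fy)
  tx <- fx - j0; ty <- fy - i0
  j0 <- pmin(pmax(j0, 1L), W); i0 <- pmin(pmax(i0, 1L), H)
  j1 <- pmin(j0 + 1L, W); i1 <- pmin(i0 + 1L, H)
  plane[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    plane[cbind(i0, j1)] * tx * (1 - ty) +
    plane[cbind(i1, j0)] * (1 - tx) * ty +
    plane[cbind(i1, j1)] * tx * ty
}

#' Extract an intensity line profile
#'
#' Samples image intensity along a straight line of given length centred on
#' a point, at the pixel pitch, by bilinear interpolation. To emulate an
#' ImageJ wide line, intensities are averaged across `width` perpendicular
#' to the line.
#'
#' @param image an `mc_image` (or a noiseless field wrapped with
#'   [mc_image()]).
#' @param center line centre in um.
#' @param angle line orientation in radians (0 = +x).
#' @param length line length in um (default 3, the standard vesicle line).
#' @param width perpendicular averaging width in um (default 0.3).
#' @param channels channel roles (or indices) to sample; default all.
#' @return An object of class `line_profile`: list with `positions` (um
#'   offsets, symmetric about 0), `intensity` (matrix positions x channels),
#'   `center`, `angle`, `line_length`.
#' @export
extract_line_profile <- function(image, center, angle, length = 3.0,
                                 width = 0.3, channels = NULL) {
  stopifnot(inherits(image, "mc_image"))
  px <- image$pixel_size
  if (is.null(channels)) channels <- names(image$channel_roles)
  n <- floor(length / px) + 1L
  positions <- (seq_len(n) - (n + 1) / 2) * px
  u <- c(cos(angle), sin(angle))
  v <- c(-sin(angle), cos(angle))
  nw <- max(1L, round(width / px))
  if (nw %% 2L == 0L) nw <- nw + 1L
  offsets <- (seq_len(nw) - (nw + 1) / 2) * px
  xs <- outer(positions, offsets, function(p, o) center[1] + p * u[1] + o * v[1])
  ys <- outer(positions, offsets, function(p, o) center[2] + p * u[2] + o * v[2])
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  ext_x <- W * px; ext_y <- H * px
  if (min(xs) < 0 || max(xs) > ext_x || min(ys) < 0 || max(ys) > ext_y)
    stop("line exits image bounds", call. = FALSE)
  intensity <- vapply(channels, function(ch) {
    plane <- image$pixels[, , channel_index(image, ch)]
    rowMeans(matrix(bilinear_sample(plane, as.numeric(xs), as.numeric(ys), px),
                    nrow = n))
  }, numeric(n))
  intensity <- matrix(intensity, nrow = n,
                      dimnames = list(NULL, as.character(channels)))
  structure(list(positions = positions, intensity = intensity,
                 line_length = length, center = center, angle = angle),
            class = "line_profile")
}

# maximum within the central third of the profile, per channel
profile_peak <- function(profile, window_frac = 1 / 3) {
  keep <- abs(profile$positions) <= profile$line_length * window_frac / 2
  apply(profile$intensity[keep, , drop = FALSE], 2, max)
}

#' Plasma-membrane reference intensity
#'
#' Returns the per-channel peak of a profile drawn across the plasma
#' membrane near a point of interest — the PM normalization value for the
#' density-ratio estimator. The profile is oriented perpendicular to the
#' membrane (radially for the circular synthetic cell) so both the vesicle
#' and its PM reference are measured by the same peak-of-profile operator.
#'
#' @param image an `mc_image` whose scene truth provides the PM contour, or
#'   any image if `pm_point` and `angle` are both supplied.
#' @param near point in um near which to take the reference (e.g. the
#'   measured vesicle centre); the nearest PM point is used.
#' @param pm_point optional explicit PM-crossing point (um).
#' @param angle optional profile orientation; defaults to the outward
#'   normal at `pm_point`.
#' @param length,width,channels as in [extract_line_profile()].
#' @return Named numeric vector of reference intensities (counts), one per
#'   channel.
#' @export
pm_reference <- function(image, near = NULL, pm_point = NULL, angle = NULL,
                         length = 3.0, width = 0.3, channels = NULL) {
  stopifnot(inherits(image, "mc_image"))
  if (is.null(pm_point)) {
    sc <- image$scene
    if (is.null(sc))
      stop("pm_reference: no scene truth attached; supply 'pm_point'", call. = FALSE)
    if (is.null(near)) near <- sc$center + c(sc$cell_radius, 0)
    dir <- near - sc$center
    nrm <- sqrt(sum(dir^2))
    dir <- if (nrm == 0) c(1, 0) else dir / nrm
    pm_point <- sc$center + sc$cell_radius * dir
    if (is.null(angle)) angle <- atan2(dir[2], dir[1])
  }
  if (is.null(angle)) stop("pm_reference: 'angle' required with 'pm_point'", call. = FALSE)
  prof <- extract_line_profile(image, pm_point, angle, length = length,
                               width = width, channels = channels)
  peaks <- profile_peak(prof)
  if (all(peaks <= 0))
    stop("degenerate PM reference: all channels are zero along the segment",
         call. = FALSE)
  peaks
}

#' Mean intensity inside a circular or rectangular ROI
#'
#' Pixel centres falling inside the region are averaged.
#'
#' @param image an `mc_image`.
#' @param channel channel role or index.
#' @param center ROI centre, um.
#' @param radius disc radius, um (for `roi_disc_mean`).
#' @return Mean intensity in counts.
#' @export
roi_disc_mean <- function(image, channel, center, radius) {
  plane <- image$pixels[, , channel_index(image, channel)]
  m <- disc_mask(center, radius, image$pixel_size, nrow(plane), ncol(plane))
  if (!any(m)) stop("empty ROI", call. = FALSE)
  mean(plane[m])
}

#' @rdname roi_disc_mean
#' @param size `c(length, width)` of the rectangle in um, `length` along
#'   `angle`.
#' @param angle rectangle orientation in radians.
#' @export
roi_rect_mean <- function(image, channel, center, size, angle = 0) {
  plane <- image$pixels[, , channel_index(image, channel)]
  px <- image$pixel_size
  g <- pixel_grid(nrow(plane), ncol(plane), px)
  X <- outer(rep(1, length(g$y)), g$x) - center[1]
  Y <- outer(g$y, rep(1, length(g$x))) - center[2]
  u <- c(cos(angle), sin(angle)); v <- c(-sin(angle), cos(angle))
  A <- X * u[1] + Y * u[2]
  B <- X * v[1] + Y * v[2]
  m <- abs(A) <= size[1] / 2 & abs(B) <= size[2] / 2
  if (!any(m)) stop("empty ROI", call. = FALSE)
  mean(plane[m])
}

#' Signal/background ratio
#'
#' Ratio of the mean intensity of a structure ROI to the mean intensity of a
#' nearby cytosol ROI, as used to compare plasma-membrane and endosome
#' labelling.
#'
#' @param structure_mean mean counts in the structure ROI.
#' @param background_mean mean counts in the cytosol background ROI; must be
#'   positive.
#' @return Dimensionless ratio.
#' @export
signal_background_ratio <- function(structure_mean, background_mean) {
  if (any(background_mean <= 0))
    stop("zero background mean: signal/background ratio undefined", call. = FALSE)
  structure_mean / background_mean
}

# deterministic cytosol point near `near`, away from PM, nucleus and all
# vesicles (truth-aware); used for background ROIs
find_background_point <- function(scene, near, offsets = c(1.5, 2, 2.5, 3),
                                  clearance = 0.5, roi_radius = 0.3) {
  # among all candidates that satisfy the hard margins (0.75 um inside the
  # PM, 0.4 um off the nucleus, `clearance` off every vesicle edge) take the
  # one with the largest clearance from any structure, so the background
  # disc sits in the cleanest nearby cytosol and membrane PSF tails are
  # negligible there
  angles <- seq(0, 2 * pi, length.out = 37L)[-37L]
  for (clr in c(clearance, 0.35)) {
    best <- NULL; best_score <- -Inf
    for (offset in offsets) {
      for (a in angles) {
        p <- near + offset * c(cos(a), sin(a))
        rad <- sqrt(sum((p - scene$center)^2))
        d_pm <- scene$cell_radius - rad
        d_nuc <- rad - scene$nucleus_radius
        if (d_pm < 0.75 + roi_radius || d_nuc < 0.4 + roi_radius) next
        d_ves <- Inf
        for (v in scene$vesicles)
          d_ves <- min(d_ves, sqrt(sum((p - v$center)^2)) - v$radius)
        if (d_ves < clr + roi_radius) next
        score <- min(d_pm, d_nuc, d_ves)
        if (score > best_score) { best_score <- score; best <- p }
      }
    }
    if (!is.null(best)) return(best)
  }
  stop("no clear cytosol background point found near the vesicle", call. = FALSE)
}

#' Signal/background ratios for a synthetic cell
#'
#' Measures one rectangular PM ROI and one disc ROI per vesicle, each paired
#' with a nearby cytosol background disc, in a single channel. ROI
#' conventions: the PM rectangle is 1.5 um along the membrane and 0.4 um
#' across it; each vesicle disc has radius `vesicle radius + 0.25` um;
#' background discs have radius 0.3 um.
#'
#' @param image an `mc_image` with scene truth.
#' @param channel channel role (default `"protein"`).
#' @return data.frame with columns `roi_kind` (`pm_rect` or `vesicle_disc`),
#'   `structure_mean`, `background_mean`, `sb_ratio`.
#' @export
measure_sb <- function(image, channel = "protein") {
  sc <- image$scene
  if (is.null(sc)) stop("measure_sb requires scene truth", call. = FALSE)
  rows <- list()
  # PM ROI on the +x side; background just inside it
  pm_point <- sc$center + c(sc$cell_radius, 0)
  pm_mean <- roi_rect_mean(image, channel, pm_point, size = c(1.5, 0.4),
                           angle = pi / 2)
  bg_point_pm <- sc$center + c(sc$cell_radius - 1.2, 0)
  bg_pm <- roi_disc_mean(image, channel, bg_point_pm, 0.3)
  rows[[1]] <- data.frame(roi_kind = "pm_rect", structure_mean = pm_mean,
                          background_mean = bg_pm,
                          sb_ratio = signal_background_ratio(pm_mean, bg_pm))
  for (v in sc$vesicles) {
    sm <- roi_disc_mean(image, channel, v$center, v$radius + 0.25)
    bp <- find_background_point(sc, v$center)
    bm <- roi_disc_mean(image, channel, bp, 0.3)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_kind = "vesicle_disc", structure_mean = sm, background_mean = bm,
      sb_ratio = signal_background_ratio(sm, bm))
  }
  do.call(rbind, rows)
}
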