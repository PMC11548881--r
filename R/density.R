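# The dye-normalized density-ratio estimator. For each vesicle, per-channel
# peak intensities from a 3 um line profile are normalized to the peak of a
# nearby PM-crossing profile in the same channel and background-subtracted;
# the density ratio is the protein quotient over the reference-dye quotient:
#
#   D = (peak_protein/PMref_protein - bg_protein/PMref_protein) /
#       (peak_ref/PMref_ref       - bg_ref/PMref_ref)
#
# Because the dye reports membrane surface area at PM-equal density, D
# estimates the protein's vesicle membrane density as a fraction of its PM
# density, independent of vesicle size and PSF width.

density_ratio_core <- function(profiles, pm_refs, backgrounds,
                               numerator, denominator, window_frac = 1 / 3) {
  peaks <- profile_peak(profiles, window_frac)
  chans <- intersect(names(peaks), intersect(names(pm_refs), names(backgrounds)))
  for (ch in c(numerator, denominator)) {
    if (!ch %in% chans)
      stop("missing channel in profiles/references/backgrounds: ", ch,
           call. = FALSE)
    if (pm_refs[[ch]] <= 0)
      stop("degenerate PM reference for channel ", ch, call. = FALSE)
  }
  peak_norm <- peaks[chans] / pm_refs[chans]
  bg_norm <- backgrounds[chans] / pm_refs[chans]
  num <- max(peak_norm[[numerator]] - bg_norm[[numerator]], 0)
  den <- peak_norm[[denominator]] - bg_norm[[denominator]]
  if (den <= 0)
    stop("unmeasurable vesicle: reference-channel numerator <= 0", call. = FALSE)
  list(peak_norm = peak_norm, bg_norm = bg_norm, ratio = num / den)
}

#' Per-vesicle membrane density ratio
#'
#' Computes the background-subtracted, PM-normalized peak ratio `D` between
#' the protein channel and the reference-dye channel for one vesicle. The
#' peak is the maximum within the central third of the line profile; a
#' negative protein numerator is clipped to 0 (a vesicle with no detectable
#' protein is a measurement of 0, not a failure), while a non-positive
#' reference numerator raises an error (no membrane was measured).
#'
#' @param profiles a `line_profile` containing both channels (see
#'   [extract_line_profile()]).
#' @param pm_refs named per-channel PM reference intensities
#'   (see [pm_reference()]).
#' @param backgrounds named per-channel cytosol background intensities.
#' @param protein,reference channel role names for the numerator and the
#'   surface-area reference.
#' @param vesicle_id optional identifier carried through.
#' @return An object of class `vesicle_measurement`: list with
#'   `peak_norm_per_channel`, `bg_norm_per_channel`, `density_ratio`,
#'   `vesicle_id`.
#' @export
vesicle_density_ratio <- function(profiles, pm_refs, backgrounds,
                                  protein = "protein",
                                  reference = "reference_dye",
                                  vesicle_id = NA_character_) {
  res <- density_ratio_core(profiles, pm_refs, backgrounds,
                            numerator = protein, denominator = reference)
  structure(list(peak_norm_per_channel = res$peak_norm,
                 bg_norm_per_channel = res$bg_norm,
                 density_ratio = res$ratio,
                 vesicle_id = vesicle_id),
            class = "vesicle_measurement")
}

#' Receptor enrichment ratio
#'
#' Same contract as [vesicle_density_ratio()] with the receptor channel as
#' numerator; values above 1 indicate enrichment on the vesicle relative to
#' the plasma membrane.
#'
#' @inheritParams vesicle_density_ratio
#' @param receptor numerator channel role.
#' @return Dimensionless enrichment ratio.
#' @export
enrichment_ratio <- function(profiles, pm_refs, backgrounds,
                             receptor = "receptor",
                             reference = "reference_dye") {
  density_ratio_core(profiles, pm_refs, backgrounds,
                     numerator = receptor, denominator = reference)$ratio
}

#' @export
print.vesicle_measurement <- function(x, ...) {
  cat(sprintf("<vesicle_measurement> D = %.4f\n", x$density_ratio))
  invisible(x)
}

#' Mean and t-based 95% confidence half-width
#'
#' @param values numeric vector, `n >= 2`.
#' @return `c(mean, ci95_halfwidth)` with
#'   `halfwidth = qt(0.975, n - 1) * sd / sqrt(n)`.
#' @export
mean_ci95 <- function(values) {
  n <- length(values)
  if (n < 2) stop("insufficient data: need at least 2 values", call. = FALSE)
  c(mean = mean(values),
    ci95_halfwidth = qt(0.975, n - 1) * sd(values) / sqrt(n))
}

#' Summarize per-vesicle density ratios
#'
#' @param measurements numeric vector of density ratios, or a list of
#'   `vesicle_measurement` objects.
#' @return An object of class `density_summary` with fields `mean`,
#'   `ci95_halfwidth`, `n`, `per_vesicle`.
#' @export
summarize_density <- function(measurements) {
  d <- if (is.numeric(measurements)) measurements
       else vapply(measurements, function(m) m$density_ratio, numeric(1))
  s <- mean_ci95(d)
  structure(list(mean = unname(s[1]), ci95_halfwidth = unname(s[2]),
                 n = length(d), per_vesicle = d),
            class = "density_summary")
}

#' @export
print.density_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Density ratio: %s +/- %s (mean +/- 95%% CI; n=%d)\n",
              format(100 * x$mean, digits = digits),
              format(100 * x$ci95_halfwidth, digits = digits), x$n))
  cat("  (percent of plasma-membrane density)\n")
  invisible(x)
}

#' @export
coef.density_summary <- function(object, ...) c(mean = object$mean)

#' @export
confint.density_summary <- function(object, parm, level = 0.95, ...) {
  hw <- qt(1 - (1 - level) / 2, object$n - 1) *
    sd(object$per_vesicle) / sqrt(object$n)
  out <- matrix(c(object$mean - hw, object$mean + hw), nrow = 1,
                dimnames = list("mean", sprintf("%g %%", 100 *
                  c((1 - level) / 2, 1 - (1 - level) / 2))))
  out
}

#' Measure one vesicle of a synthetic cell image
#'
#' Truth-aware orchestration of the measurement layer: extracts the 3 um
#' multi-channel line profile at the vesicle centre (oriented tangentially,
#' i.e. maximizing distance of the line ends to the PM contour), takes the
#' PM reference from the nearest PM-crossing profile, measures the cytosol
#' background from a clear disc near the vesicle, and computes the density
#' ratio (and, when a receptor channel is present, the enrichment ratio).
#'
#' @param image an `mc_image` with scene truth (or `annotations` supplied).
#' @param vesicle index of the vesicle to measure (default 1; one vesicle is
#'   sampled per cell/image).
#' @param annotations optional `cell_scene` overriding `image$scene`.
#' @param protein,reference channel roles for the density ratio.
#' @param length,width profile geometry, um.
#' @return One-row data.frame: `vesicle_id`, per-channel peaks, backgrounds
#'   and PM references, `density_ratio`, `enrichment` (NA without a receptor
#'   channel), and ground-truth columns `truth_rho_*` when available.
#' @export
measure_vesicle <- function(image, vesicle = 1L, annotations = NULL,
                            protein = "protein", reference = "reference_dye",
                            length = 3.0, width = 0.3) {
  sc <- if (!is.null(annotations)) annotations else image$scene
  if (is.null(sc)) stop("measure_vesicle requires scene truth or annotations",
                        call. = FALSE)
  if (vesicle > base::length(sc$vesicles))
    stop("vesicle index out of range", call. = FALSE)
  v <- sc$vesicles[[vesicle]]
  radial <- atan2(v$center[2] - sc$center[2], v$center[1] - sc$center[1])
  prof <- extract_line_profile(image, v$center, angle = radial + pi / 2,
                               length = length, width = width)
  refs <- pm_reference(image, near = v$center, length = length, width = width)
  bp <- find_background_point(sc, v$center)
  chans <- names(image$channel_roles)
  bgs <- vapply(chans, function(ch) roi_disc_mean(image, ch, bp, 0.3),
                numeric(1))
  vm <- vesicle_density_ratio(prof, refs, bgs, protein = protein,
                              reference = reference,
                              vesicle_id = sprintf("v%03d", vesicle))
  enr <- if ("receptor" %in% chans)
    enrichment_ratio(prof, refs, bgs, reference = reference) else NA_real_
  out <- data.frame(vesicle_id = vm$vesicle_id,
                    density_ratio = vm$density_ratio,
                    enrichment = enr)
  for (ch in chans) {
    out[[paste0("peak_norm_", ch)]] <- vm$peak_norm_per_channel[[ch]] %||%
      NA_real_
    out[[paste0("bg_norm_", ch)]] <- vm$bg_norm_per_channel[[ch]] %||% NA_real_
    out[[paste0("truth_rho_", ch)]] <- v$rho[[ch]]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
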