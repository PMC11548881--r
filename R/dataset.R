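# Dataset I/O: one multi-page TIFF (one page per channel, uncompressed) plus
# a ground-truth JSON sidecar holding pixel size, channel roles, generator
# seeds, a config echo and the full vesicle truth. The TIFF stores pixels
# only; all metadata lives in the JSON, and a round trip reproduces the
# raster bit-exactly.

#' Write a simulated dataset to disk
#'
#' @param image an `mc_image`.
#' @param out_prefix path prefix; `<prefix>.tif` and `<prefix>.json` are
#'   written.
#' @param truth optional `cell_scene`; defaults to `image$scene`.
#' @return Invisibly, the two paths written.
#' @export
write_dataset <- function(image, out_prefix, truth = image$scene) {
  stopifnot(inherits(image, "mc_image"))
  tif <- paste0(out_prefix, ".tif")
  jsn <- paste0(out_prefix, ".json")
  maxval <- 2^image$bit_depth - 1
  planes <- lapply(seq_len(dim(image$pixels)[3]),
                   function(k) image$pixels[, , k] / maxval)
  ok <- tryCatch(tiff::writeTIFF(planes, tif,
                                 bits.per.sample = image$bit_depth,
                                 compression = "none"),
                 error = function(e) stop("failed to write TIFF at ", tif,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  meta <- list(pixel_size_um = image$pixel_size,
               channel_roles = as.list(image$channel_roles),
               bit_depth = image$bit_depth,
               noise_seed = image$seed,
               config = if (!is.null(image$config))
                 unclass(image$config)[c("pixel_size", "psf_sigma",
                                         "photon_scale", "read_noise_sd",
                                         "bit_depth")] else NULL,
               truth = if (!is.null(truth)) scene_to_list(truth) else NULL)
  # digits = I(17): lossless double round trip, so a re-render from the
  # stored truth and seed reproduces the raster bit-exactly
  tryCatch(jsonlite::write_json(meta, jsn, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE),
           error = function(e) stop("failed to write JSON at ", jsn, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(c(tif = tif, json = jsn))
}

scene_to_list <- function(scene) {
  list(image_size_um = scene$image_size_um,
       center = scene$center,
       cell_radius = scene$cell_radius,
       nucleus_radius = scene$nucleus_radius,
       pm_density = as.list(scene$pm_density),
       cytosol_level = as.list(scene$cytosol_level),
       seed = scene$seed,
       vesicles = lapply(scene$vesicles, function(v)
         list(center = v$center, radius = v$radius, rho = as.list(v$rho),
              lumen_level = as.list(v$lumen_level),
              kind_label = v$kind_label)))
}

scene_from_list <- function(tr) {
  sc <- build_cell_geometry(image_size_um = tr$image_size_um,
                            cell_radius = tr$cell_radius,
                            nucleus_radius = tr$nucleus_radius,
                            center = unlist(tr$center),
                            pm_density = unlist(tr$pm_density),
                            cytosol_level = unlist(tr$cytosol_level),
                            seed = tr$seed)
  sc$vesicles <- lapply(tr$vesicles, function(v)
    list(center = unlist(v$center), radius = v$radius,
         rho = unlist(v$rho), lumen_level = unlist(v$lumen_level),
         kind_label = v$kind_label))
  sc
}

#' Read a dataset written by [write_dataset()]
#'
#' @param prefix path prefix used at write time.
#' @return An `mc_image` with the ground-truth scene attached (when the
#'   sidecar recorded one).
#' @export
read_dataset <- function(prefix) {
  tif <- paste0(prefix, ".tif")
  jsn <- paste0(prefix, ".json")
  if (!file.exists(tif) || !file.exists(jsn))
    stop("dataset not found at prefix ", prefix, call. = FALSE)
  meta <- jsonlite::read_json(jsn)
  planes <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  pixels <- array(0L, dim = c(dim(planes[[1]]), length(planes)))
  for (k in seq_along(planes)) pixels[, , k] <- planes[[k]]
  roles <- vapply(meta$channel_roles, as.integer, integer(1))
  img <- mc_image(pixels, pixel_size = as.numeric(meta$pixel_size_um),
                  channel_roles = roles,
                  bit_depth = as.integer(meta$bit_depth),
                  scene = if (!is.null(meta$truth))
                    scene_from_list(meta$truth) else NULL)
  img$seed <- if (!is.null(meta$noise_seed)) as.integer(meta$noise_seed)
              else NULL
  img
}
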