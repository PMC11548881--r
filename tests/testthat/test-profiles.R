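test_that("profiles on a uniform image are constant with the expected sampling", {
  img <- mc_image(array(7, c(100, 100, 1)), pixel_size = 0.1,
                  channel_roles = c(protein = 1L))
  pr <- extract_line_profile(img, center = c(5, 5), angle = 0.3, length = 3)
  expect_length(pr$positions, 31)  # floor(3.0 / 0.1) + 1
  expect_true(all(diff(pr$positions) > 0))
  expect_equal(pr$positions, -rev(pr$positions))
  expect_true(all(abs(pr$intensity - 7) < 1e-12))
})

test_that("a line leaving the image raises a geometry error", {
  img <- mc_image(array(1, c(50, 50, 1)), 0.1, c(protein = 1L))
  expect_error(extract_line_profile(img, center = c(0.5, 2.5), angle = 0),
               "bounds")
})

test_that("vesicle profiles match the analytic blurred-circle field", {
  r <- 0.4; sigma <- 0.15; d_ref <- 150000
  img <- noiseless_vesicle_image(rho_protein = 0.5, radius = r,
                                 psf_sigma = sigma)
  v <- img$scene$vesicles[[1]]
  pr <- extract_line_profile(img, center = v$center, angle = 0.7,
                             length = 3, width = 0.1,
                             channels = "reference_dye")
  expected <- analytic_circle_intensity(abs(pr$positions), r, d_ref,
                                        effective_sigma(sigma, 0.1), 0.1)
  keep <- expected > 0.1 * max(expected)
  # residual slack covers grid-alignment wobble of the rasterized circle
  expect_lt(max(abs(pr$intensity[keep, 1] / expected[keep] - 1)), 0.05)
})

test_that("PM reference equals the analytic line-spread peak and is symmetric", {
  sc <- build_cell_geometry(pm_density = c(protein = 94000, reference_dye = 150000),
                            cytosol_level = c(protein = 0, reference_dye = 0))
  ic <- imaging_config(read_noise_sd = 0)
  f <- render_field(sc, ic)
  img <- mc_image(f, 0.1, ic$channel_roles, scene = sc)
  img$config <- ic
  ref <- pm_reference(img, near = sc$center + c(0, 5))
  # the PM is a circle of radius 7.5 um; evaluate the same closed form at
  # the membrane (distance == radius)
  expected <- analytic_circle_intensity(7.5, 7.5, 94000,
                                        effective_sigma(0.15, 0.1), 0.1)
  expect_equal(unname(ref[["protein"]]), expected, tolerance = 0.05)
  ref2 <- pm_reference(img, near = sc$center + c(-3, 4))
  expect_equal(unname(ref2[["protein"]]), unname(ref[["protein"]]),
               tolerance = 0.05)
  # degenerate reference on an all-zero image
  dark <- mc_image(array(0, dim = dim(f)), 0.1, ic$channel_roles, scene = sc)
  expect_error(pm_reference(dark, near = sc$center + c(0, 5)), "degenerate")
})

test_that("signal/background ratios follow their definition", {
  expect_equal(signal_background_ratio(40, 10), 4)
  expect_error(signal_background_ratio(40, 0), "background")
  # a structure ROI drawn on pure cytosol gives a ratio of ~1
  sc <- build_cell_geometry()
  img <- render_image(sc, imaging_config(), seed = 41)
  a <- roi_disc_mean(img, "protein", sc$center + c(0, 5), 0.3)
  b <- roi_disc_mean(img, "protein", sc$center + c(0, -5), 0.3)
  expect_equal(signal_background_ratio(a, b), 1, tolerance = 0.1)
})

test_that("PM regions outshine dim vesicles in signal/background terms", {
  ratios <- lapply(1:6, function(s) {
    sc <- build_cell_geometry()
    sc <- place_vesicles(sc, 4, rho = list(protein = 0.2, reference_dye = 1),
                         seed = 60 + s)
    img <- render_image(sc, imaging_config(), seed = 160 + s)
    measure_sb(img, "protein")
  })
  sb <- do.call(rbind, ratios)
  expect_gt(median(sb$sb_ratio[sb$roi_kind == "pm_rect"]),
            median(sb$sb_ratio[sb$roi_kind == "vesicle_disc"]))
})
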