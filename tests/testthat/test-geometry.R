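# polygon area by the shoelace formula (independent of the generator)
shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

test_that("cell geometry has the requested shape and is deterministic", {
  sc <- build_cell_geometry(image_size_um = 24, cell_radius = 10,
                            nucleus_radius = 4, seed = 1)
  expect_s3_class(sc, "cell_scene")
  expect_equal(shoelace(sc$pm_contour), pi * 100, tolerance = 0.01)
  # contour encloses the nucleus
  rad <- sqrt(rowSums(sweep(sc$pm_contour, 2, sc$center)^2))
  expect_true(all(rad > sc$nucleus_radius))
  sc2 <- build_cell_geometry(image_size_um = 24, cell_radius = 10,
                             nucleus_radius = 4, seed = 1)
  expect_identical(sc, sc2)
})

test_that("invalid geometry parameters are rejected by name", {
  expect_error(build_cell_geometry(cell_radius = 10, nucleus_radius = 12,
                                   image_size_um = 30),
               "nucleus_radius")
  expect_error(build_cell_geometry(cell_radius = -1), "cell_radius")
  expect_error(build_cell_geometry(image_size_um = 12, cell_radius = 7.5),
               "cell_radius")
})

test_that("vesicle placement respects margins, overlap and truth recording", {
  sc <- build_cell_geometry()
  sc <- place_vesicles(sc, 12, rho = list(protein = 0.20, reference_dye = 1.0),
                       seed = 3)
  expect_length(sc$vesicles, 12)
  for (v in sc$vesicles) {
    expect_equal(unname(v$rho[["protein"]]), 0.20)
    expect_equal(unname(v$rho[["reference_dye"]]), 1.0)
    radial <- sqrt(sum((v$center - sc$center)^2))
    # at least one vesicle diameter away from the PM contour
    expect_gte(sc$cell_radius - radial, 2 * v$radius)
    # entirely outside the nucleus
    expect_gte(radial - v$radius, sc$nucleus_radius)
  }
  centers <- t(vapply(sc$vesicles, `[[`, numeric(2), "center"))
  radii <- vapply(sc$vesicles, `[[`, numeric(1), "radius")
  d <- as.matrix(dist(centers))
  sep <- d - outer(radii, radii, "+")
  diag(sep) <- Inf
  expect_true(all(sep > 0))  # pairwise non-overlapping

  expect_identical(place_vesicles(sc, 0), sc)
  expect_error(place_vesicles(build_cell_geometry(), 400,
                              radius_range = c(0.55, 0.6), seed = 1),
               "placement failed")
})

test_that("receptor-positive vesicles carry the enrichment ground truth", {
  sc <- build_cell_geometry(
    pm_density = c(protein = 94000, reference_dye = 150000, receptor = 120000),
    cytosol_level = c(protein = 8000, reference_dye = 2500, receptor = 3000))
  sc <- place_vesicles(sc, 6, rho = list(protein = 0.28, reference_dye = 1.0,
                                         receptor = 3.0),
                       kind_label = "receptor_positive", seed = 2)
  expect_true(all(vapply(sc$vesicles, function(v) v$rho[["receptor"]],
                         numeric(1)) == 3.0))
  expect_true(all(vapply(sc$vesicles, `[[`, character(1), "kind_label") ==
                    "receptor_positive"))
})

test_that("zero-clipped normal heterogeneity matches the requested moments", {
  for (m in list(c(0.20, 0.2663), c(0.28, 0.3841), c(0.64, 0.7540))) {
    set.seed(99)
    x <- rclipnorm(1e5, m[1], m[2])
    expect_true(all(x >= 0))
    expect_equal(mean(x), m[1], tolerance = 0.01)
    expect_equal(sd(x), m[2], tolerance = 0.01)
  }
  # a vesicle population at mean 0.2 has a sizeable fraction with no protein
  set.seed(100)
  expect_gt(mean(rclipnorm(1e4, 0.20, 0.2663) == 0), 0.3)
})
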