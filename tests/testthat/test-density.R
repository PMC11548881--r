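# hand-built profile fixture: constant intensities per channel
flat_profiles <- function(values, length = 3) {
  n <- 31L
  structure(list(positions = (seq_len(n) - 16) * 0.1,
                 intensity = sapply(values, rep, n),
                 line_length = length, center = c(0, 0), angle = 0),
            class = "line_profile")
}

test_that("the density ratio follows its normalization arithmetic", {
  # peak_norm 0.25 / bg 0.05 over peak_norm 1.05 / bg 0.05 -> D = 0.20
  pr <- flat_profiles(c(protein = 25, reference_dye = 105))
  refs <- c(protein = 100, reference_dye = 100)
  bgs <- c(protein = 5, reference_dye = 5)
  vm <- vesicle_density_ratio(pr, refs, bgs)
  expect_equal(vm$density_ratio, 0.20)
  expect_equal(unname(vm$peak_norm_per_channel[["protein"]]), 0.25)

  # identical channels -> D = 1
  pr2 <- flat_profiles(c(protein = 80, reference_dye = 80))
  expect_equal(vesicle_density_ratio(pr2, c(protein = 90, reference_dye = 90),
                                     c(protein = 10, reference_dye = 10))$density_ratio,
               1)

  # protein at pure background clips to 0; reference at background errors
  pr3 <- flat_profiles(c(protein = 5, reference_dye = 105))
  expect_equal(vesicle_density_ratio(pr3, refs, bgs)$density_ratio, 0)
  pr4 <- flat_profiles(c(protein = 25, reference_dye = 5))
  expect_error(vesicle_density_ratio(pr4, refs, bgs), "unmeasurable")
})

test_that("enrichment ratio mirrors the density contract on the receptor channel", {
  pr <- flat_profiles(c(receptor = 305, reference_dye = 105))
  refs <- c(receptor = 100, reference_dye = 100)
  bgs <- c(receptor = 5, reference_dye = 5)
  expect_equal(enrichment_ratio(pr, refs, bgs), 3.0)
  # all-background receptor channel -> 0
  pr0 <- flat_profiles(c(receptor = 5, reference_dye = 105))
  expect_equal(enrichment_ratio(pr0, refs, bgs), 0)
})

test_that("noiseless D equals truth independent of PSF width and vesicle size", {
  for (sigma in c(0.1, 0.15, 0.25)) {
    for (r in c(0.25, 0.4, 0.6)) {
      img <- noiseless_vesicle_image(rho_protein = 0.64, radius = r,
                                     psf_sigma = sigma)
      m <- measure_vesicle(img)
      expect_lt(abs(m$density_ratio - 0.64) / 0.64, 1e-6)
    }
  }
})

test_that("D is invariant to per-channel gain", {
  img <- noiseless_vesicle_image(rho_protein = 0.37, radius = 0.4)
  d0 <- measure_vesicle(img)$density_ratio
  img2 <- img
  img2$pixels[, , "protein"] <- img2$pixels[, , "protein"] * 3.7
  expect_equal(measure_vesicle(img2)$density_ratio, d0, tolerance = 1e-12)
  img3 <- img
  img3$pixels[, , "reference_dye"] <- img3$pixels[, , "reference_dye"] * 0.41
  expect_equal(measure_vesicle(img3)$density_ratio, d0, tolerance = 1e-12)
})

test_that("noiseless D increases strictly with ground-truth density", {
  ds <- vapply(c(0.1, 0.2, 0.4, 0.8), function(rho) {
    measure_vesicle(noiseless_vesicle_image(rho_protein = rho))$density_ratio
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("density summaries report t-based confidence intervals", {
  s <- summarize_density(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$ci95_halfwidth, qt(0.975, 2) / sqrt(3))  # sd = 1
  expect_equal(s$ci95_halfwidth, 2.484138, tolerance = 1e-6)
  expect_equal(s$n, 3)
  expect_equal(summarize_density(rep(0.4, 5))$ci95_halfwidth, 0)
  expect_error(summarize_density(0.2), "at least 2")
  expect_equal(unname(coef(summarize_density(c(1, 2, 3)))), 2)
  ci <- confint(summarize_density(c(1, 2, 3)))
  expect_equal(unname(ci[1, ]), c(2 - 2.484138, 2 + 2.484138),
               tolerance = 1e-6)
})

test_that("mean_ci95 matches the textbook formula", {
  x <- c(0.12, 0.34, 0.19, 0.08, 0.27)
  out <- mean_ci95(x)
  expect_equal(unname(out[1]), mean(x))
  expect_equal(unname(out[2]), qt(0.975, 4) * sd(x) / sqrt(5))
})
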