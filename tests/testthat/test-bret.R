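test_that("raw and net BRET follow their definitions", {
  expect_equal(raw_bret(500, 1000), 0.5)
  expect_equal(raw_bret(0, 1000), 0)
  expect_error(raw_bret(500, 0), "donor")
  expect_error(raw_bret(-1, 100), ">= 0")
  expect_equal(net_bret(0.5, 0.2), 0.3)
  expect_equal(net_bret(0.2, 0.2), 0)        # donor-only against itself
  expect_equal(net_bret(0.15, 0.2), -0.05)   # negatives are not clipped
})

test_that("raw BRET is invariant to luciferase expression level", {
  acc <- c(120, 340, 11); don <- c(900, 1100, 60)
  for (k in c(0.1, 3, 1e4)) {
    expect_equal(raw_bret(k * acc, k * don), raw_bret(acc, don),
                 tolerance = 1e-12)
  }
})

test_that("trace construction validates times and injections", {
  expect_error(bret_trace(c(0, 1, 1), rep(10, 3), rep(1, 3)),
               "strictly increasing")
  expect_error(bret_trace(0:2, rep(10, 3), rep(1, 3),
                          injections = data.frame(time = 5, label = "DA")),
               "within the trace span")
})

test_that("agonist delta recovers step responses and rejects bad windows", {
  flat <- simulate_kinetic_trace(baseline = 0.1, duration = 200,
                                 noise_frac = 0, seed = 1)
  expect_equal(agonist_delta(flat, c(0, 50), c(100, 150)), 0)

  step <- simulate_kinetic_trace(
    baseline = 0.1,
    injections = list(list(time = 60, target = 0.2, tau = 1e-9, label = "DA")),
    duration = 300, noise_frac = 0, seed = 1)
  expect_equal(agonist_delta(step, c(0, 50), c(100, 150)), 0.1,
               tolerance = 1e-9)

  # rise then reversal: after the antagonist/GDP injection the response
  # relaxes back to baseline, so the late-window delta vanishes
  rev <- simulate_kinetic_trace(
    baseline = 0.1,
    injections = list(list(time = 60, target = 0.2, tau = 5, label = "DA"),
                      list(time = 150, target = 0.1, tau = 5, label = "GDP")),
    duration = 300, noise_frac = 0.003, seed = 2)
  expect_equal(agonist_delta(rev, c(0, 50), c(80, 140)), 0.1,
               tolerance = 0.02)
  expect_equal(agonist_delta(rev, c(0, 50), c(250, 300)), 0, tolerance = 0.01)

  expect_error(agonist_delta(step, c(0, 70), c(100, 150)), "precede")
  expect_error(agonist_delta(step, c(0, 50), c(40, 80)), "overlap")
  expect_error(agonist_delta(flat, c(0, 50), c(150.2, 150.4)), "empty")
})

test_that("bystander panels reflect their colocalization fractions", {
  # noiseless: net BRET is exactly amplitude * fraction, order preserved
  fr <- c(PM = 1, LE = 0.2, ER = 0.03)
  wells <- simulate_bystander_panel(fr, amplitude_max = 0.5, noise_sd = 0,
                                    n_replicates = 3, seed = 3)
  net <- panel_net(wells)
  means <- tapply(net$net_bret, net$compartment, mean)
  expect_equal(as.numeric(means[names(fr)]), 0.5 * unname(fr),
               tolerance = 1e-12)
  expect_true(means["PM"] > means["LE"] && means["LE"] > means["ER"])

  # fraction 0 -> replicates centred on 0
  w0 <- simulate_bystander_panel(c(X = 0), noise_sd = 0.01,
                                 n_replicates = 8, seed = 4)
  n0 <- panel_net(w0)
  expect_lt(abs(mean(n0$net_bret)), 0.02)

  expect_error(simulate_bystander_panel(c(PM = 1.2)), "fractions")
  expect_error(panel_net(wells[wells$compartment != "donor_only", ]),
               "donor-only")
})

test_that("panel means recover the simulated truth across seeds", {
  fr <- c(EE = 0.25, RE = 0.3, LE = 0.2)
  amplitude <- 0.5; sdn <- 0.01; nrep <- 6
  hits <- 0
  for (s in 1:40) {
    net <- panel_net(simulate_bystander_panel(fr, amplitude_max = amplitude,
                                              noise_sd = sdn,
                                              n_replicates = nrep, seed = s))
    means <- tapply(net$net_bret, net$compartment, mean)
    err <- abs(means[names(fr)] - amplitude * fr)
    hits <- hits + all(err <= 2 * sdn / sqrt(nrep) + 2 * sdn / sqrt(nrep))
  }
  # each compartment mean carries noise from its own wells and the shared
  # donor-only correction; 2 SE of that combination should hold most times
  expect_gt(hits / 40, 0.8)
})

test_that("experiment presets drive the bystander pipeline end to end", {
  ex <- run_experiment("bystander_panel", seed = 5)
  expect_s3_class(ex, "eq_experiment")
  expect_length(ex$fdr$p_values, 9)  # 3 compartments x 3 agonists
  expect_identical(ex$fdr$method, "BKY two-stage")
  # under the null (no agonist effect), discoveries should be rare
  expect_lte(sum(ex$fdr$rejected), 1)
})
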