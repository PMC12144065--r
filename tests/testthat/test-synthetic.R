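test_that("a scenario with no dynamics and no noise renders identical frames", {
  scn <- scenario(constriction_rate = 0, fusion_rate = 0, noise_sd = 0,
                  frame_count = 5, seed = 1)
  sim <- simulate_vacuole_sequence(scn)
  expect_equal(nrow(sim$events), 0)
  for (t in 2:5)
    expect_identical(sim$stack$frames[, , t], sim$stack$frames[, , 1])
})

test_that("the generator is bit-deterministic under a fixed seed", {
  a <- simulate_vacuole_sequence(scenario_presets("unpollinated", seed = 17))
  b <- simulate_vacuole_sequence(scenario_presets("unpollinated", seed = 17))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$events, b$events)
  c_ <- simulate_vacuole_sequence(scenario_presets("unpollinated", seed = 18))
  expect_false(identical(a$stack$frames, c_$stack$frames))
})

test_that("logged constrictions equal a brute-force rescan of the render", {
  # noiseless movie; the scan is an independent reimplementation of the
  # "new border completely across the cell" counting rule
  scn <- scenario_presets("unpollinated", seed = 7, noise_sd = 0)
  sim <- simulate_vacuole_sequence(scn)
  found <- scan_borders_bruteforce(sim$stack$frames, sim$cell_mask)
  truth <- sim$events[sim$events$kind == "constriction", ]
  expect_equal(nrow(found), nrow(truth))
  expect_equal(sort(found[, "frame"]), sort(truth$frame))
})

test_that("event log respects time bounds, ordering, and positions", {
  for (seed in 1:5) {
    sim <- simulate_vacuole_sequence(scenario_presets("e64d", seed = seed))
    ev <- sim$events
    expect_true(all(ev$time_s >= 0 & ev$time_s <= 590))
    expect_true(!is.unsorted(ev$time_s))
    expect_true(all(ev$position >= 0 & ev$position <= 1))
    expect_true(all(ev$kind %in% c("constriction", "fusion")))
    # every constriction persists at least 2 frames
    expect_true(all(ev$duration_frames[ev$kind == "constriction"] >= 2))
  }
})

test_that("pollinated movies have strictly fewer constrictions (same seed)", {
  for (seed in c(1, 7, 23)) {
    unp <- simulate_vacuole_sequence(scenario_presets("unpollinated", seed = seed))
    pol <- simulate_vacuole_sequence(scenario_presets("pollinated", seed = seed))
    expect_lt(sum(pol$events$kind == "constriction"),
              sum(unp$events$kind == "constriction"))
  }
})

test_that("presets encode the published orderings and identities", {
  unp <- scenario_presets("unpollinated")
  mock <- scenario_presets("mock")
  expect_equal(mock$constriction_rate, unp$constriction_rate)
  expect_equal(mock$fusion_rate, unp$fusion_rate)
  # zero-dose wortmannin is mock
  w0 <- scenario_presets("wortmannin", dose_um = 0)
  expect_equal(w0[setdiff(names(w0), "name")], mock[setdiff(names(mock), "name")])
  # dose series: monotone non-increasing constriction rate
  rates <- vapply(c(1, 10, 33, 100, 500), function(d)
    scenario_presets("wortmannin", dose_um = d)$constriction_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  # e64d > mock = unpollinated > pdmp ~ wortmannin_500 ~ pollinated
  e <- scenario_presets("e64d")$constriction_rate
  p <- scenario_presets("pdmp")$constriction_rate
  w5 <- scenario_presets("wortmannin", dose_um = 500)$constriction_rate
  pol <- scenario_presets("pollinated")$constriction_rate
  expect_true(e > mock$constriction_rate)
  expect_true(all(c(p, w5, pol) < mock$constriction_rate))
  expect_error(scenario_presets("nope"), "unknown preset")
})

test_that("scenario validation rejects impossible inputs", {
  expect_error(scenario(frame_count = 1), "at least 2")
  expect_error(scenario(constriction_rate = -1), "nonnegative")
  expect_error(scenario(frame_interval_s = 0), "positive")
  expect_error(scenario(width_px = 5), "too small")
})

test_that("NCC draws from the observation model behave as Beta proportion", {
  # concentration limit: huge kappa pins draws at mu
  tr <- ssm_truth(mu = rep(0.7, 5), kappa = 1e6, n_cells_control = 200,
                  n_cells_experimental = 2, seed = 2)
  sim <- simulate_ncc_series(tr)
  expect_true(all(abs(rowMeans(sim$control) - 0.7) < 1e-2))
  # kappa = 2, mu = 0.5 reduces to Uniform(0,1): KS test vs uniform
  tr2 <- ssm_truth(mu = rep(0.5, 10), kappa = 2, n_cells_control = 100,
                   n_cells_experimental = 2, seed = 3)
  sim2 <- simulate_ncc_series(tr2)
  ks <- suppressWarnings(stats::ks.test(as.numeric(sim2$control), "punif"))
  expect_gt(ks$p.value, 0.01)
  # delta = 0: the two groups are exchangeable
  tr3 <- ssm_truth(mu = ncc_decay_path(20), delta = rep(0, 20),
                   kappa = 30, n_cells_control = 25,
                   n_cells_experimental = 25, seed = 4)
  sim3 <- simulate_ncc_series(tr3)
  ks2 <- suppressWarnings(
    stats::ks.test(as.numeric(sim3$control), as.numeric(sim3$experimental)))
  expect_gt(ks2$p.value, 0.01)
  # open-interval support and reproducibility
  expect_true(all(sim3$control > 0 & sim3$control < 1))
  expect_identical(simulate_ncc_series(tr3)$control, sim3$control)
  expect_error(ssm_truth(mu = rep(0.95, 3), delta = rep(0.1, 3)), "0, 1")
})

test_that("pollen assay trajectories follow the stated kinetics", {
  # noiseless: exact closed form at t = 0 and t -> infinity
  sim <- simulate_pollen_assay(L0 = 20, plateau_rate = 40, tau = 3,
                               noise_sd = 0, duration = 15)
  expect_equal(sim$track$width_um[1], 20)
  expect_equal(nrow(sim$track), 16)           # 0-inclusive 1-min grid
  expect_equal(sim$track$time_min, 0:15)
  far <- simulate_pollen_assay(L0 = 20, plateau_rate = 40, tau = 3,
                               noise_sd = 0, duration = 300)
  expect_equal(tail(far$track$width_um, 1), 20 * 1.4, tolerance = 1e-4)
  # grid size against an enumeration oracle for several settings
  for (cfg in list(c(1, 15), c(0.5, 10), c(2, 15))) {
    s <- simulate_pollen_assay(interval = cfg[1], duration = cfg[2], noise_sd = 0)
    expect_equal(nrow(s$track), length(seq(0, cfg[2], by = cfg[1])))
  }
  expect_error(simulate_pollen_assay(L0 = 0), "positive")
  expect_error(simulate_pollen_assay(duration = 0.5, interval = 1), "at least")
})

test_that("event logs round-trip through CSV", {
  sim <- simulate_vacuole_sequence(scenario_presets("unpollinated", seed = 5))
  p <- withr::local_tempfile(fileext = ".csv")
  write_event_log(sim$events, p)
  back <- read_event_log(p)
  expect_equal(back$time_s, sim$events$time_s)
  expect_equal(back$kind, sim$events$kind)
})
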