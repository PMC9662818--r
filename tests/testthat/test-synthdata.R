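test_that("identical config and seed give identical bundles", {
  cfg <- sim_config(n_units = 3, social_neuron_fraction = 0.5)
  b1 <- simulate_experiment(cfg, seed = 5)
  b2 <- simulate_experiment(cfg, seed = 5)
  expect_identical(lapply(b1$units, `[[`, "spikes"),
                   lapply(b2$units, `[[`, "spikes"))
  expect_identical(b1$tracking$EE$parts$nose, b2$tracking$EE$parts$nose)
  expect_identical(b1$targets, b2$targets)
  b3 <- simulate_experiment(cfg, seed = 6)
  expect_false(identical(lapply(b1$units, `[[`, "spikes"),
                         lapply(b3$units, `[[`, "spikes")))
})

test_that("spike process is calibrated: Poisson mean and zone rates", {
  # 2 Hz constant over 600 s: mean count 1200 within sampling error
  spec <- unit_spec(baseline_rate = 2, burst_propensity = 0)
  segs <- data.frame(start = 0, end = 600, rate = 2)
  set.seed(42)
  counts <- replicate(200, length(simulate_unit_spikes(spec, segs, 600)))
  se <- sqrt(1200 / 200)  # Poisson variance / replicates
  expect_lt(abs(mean(counts) - 1200), 4 * se)

  # zone-dependent rates calibrated segment by segment
  segs2 <- data.frame(start = c(0, 100, 200), end = c(100, 200, 300),
                      rate = c(1, 6, 2))
  set.seed(43)
  n1 <- n2 <- n3 <- numeric(100)
  for (r in 1:100) {
    sp <- simulate_unit_spikes(spec, segs2, 300)
    n1[r] <- sum(sp < 100); n2[r] <- sum(sp >= 100 & sp < 200)
    n3[r] <- sum(sp >= 200)
  }
  for (x in list(c(mean(n1), 100), c(mean(n2), 600), c(mean(n3), 200)))
    expect_lt(abs(x[1] - x[2]), 3 * sqrt(x[2] / 100))
})

test_that("degenerate and bursty spike processes behave as specified", {
  spec0 <- unit_spec(baseline_rate = 0, rest_rate = 0, burst_propensity = 0)
  expect_length(simulate_unit_spikes(spec0, data.frame(
    start = 0, end = 100, rate = 0), 100), 0)
  expect_error(simulate_unit_spikes(spec0, data.frame(
    start = 0, end = 100, rate = -1), 100), "negative")

  segs <- data.frame(start = 0, end = 600, rate = 3)
  s_burst <- simulate_unit_spikes(unit_spec(burst_propensity = 0.5), segs,
                                  600, seed = 9)
  s_flat <- simulate_unit_spikes(unit_spec(burst_propensity = 0), segs,
                                 600, seed = 9)
  bp <- function(s) burst_proportion(s, 10)$burst_proportion
  expect_gt(bp(s_burst), bp(s_flat) + 10)
})

test_that("simulated experiments satisfy their structural invariants", {
  b <- small_bundle()
  ep <- session_epochs(b$layout)
  t_total <- max(ep$end)
  for (u in b$units) {
    expect_true(all(diff(u$spikes) >= 0))
    expect_true(all(u$spikes >= 0 & u$spikes < t_total))
  }
  for (tr in b$tracking) {
    for (p in tr$parts) {
      expect_true(all(p$x >= 0 & p$x <= b$layout$chamber_length))
      expect_true(all(p$y >= 0 & p$y <= b$layout$chamber_width))
    }
  }
  # every one of the six targets accrues at least 20 s of valid sniffing
  ev <- small_events()
  expect_length(ev$sniff, 6)
  for (k in names(ev$sniff))
    expect_gte(interval_duration(ev$sniff[[k]]), 20)
})

test_that("write/read round-trips a bundle through the on-disk dialects", {
  b <- simulate_experiment(sim_config(n_units = 5), seed = 77)
  # force one empty unit to exercise the header-only spike file
  b$units[[2]]$spikes <- numeric(0)
  dir <- withr::local_tempdir()
  write_experiment(b, dir)
  expect_length(list.files(file.path(dir, "spikes")), 5)
  expect_identical(readLines(file.path(dir, "spikes", "unit_0002.csv")),
                   "spike_time_s")
  b2 <- read_experiment(dir)
  expect_equal(b2$layout, b$layout)
  expect_identical(b2$targets$target, b$targets$target)
  for (i in seq_along(b$units)) {
    expect_equal(b2$units[[i]]$spikes, b$units[[i]]$spikes,
                 tolerance = 1e-9)
    expect_equal(b2$units[[i]]$hvw, b$units[[i]]$hvw, tolerance = 1e-9)
    expect_equal(b2$units[[i]]$l_ratio, b$units[[i]]$l_ratio,
                 tolerance = 1e-9)
  }
  for (ses in names(b$tracking)) {
    expect_equal(b2$tracking[[ses]]$times, b$tracking[[ses]]$times,
                 tolerance = 1e-9)
    expect_equal(b2$tracking[[ses]]$parts$nose$x,
                 b$tracking[[ses]]$parts$nose$x, tolerance = 1e-9)
  }
  for (id in names(b$truth))
    expect_equal(b2$truth[[id]]$target_gains, b$truth[[id]]$target_gains,
                 tolerance = 1e-9)
})
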