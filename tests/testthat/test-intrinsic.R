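test_that("triangular spikes have the analytic width at half height", {
  # hand-built trace: rise at slope a from -60 mV to +20, fall at slope b
  dt <- 5e-5
  a <- 40; b <- 20  # mV/ms
  up <- seq(-60, 20, by = a * dt * 1000)
  down <- seq(20, -70, by = -b * dt * 1000)
  v <- c(rep(-60, 2000), up, down[-1], rep(-70, 2000))
  f <- detect_spikes_and_features(v, dt)
  expect_equal(nrow(f), 1)
  # dV/dt jumps 0 -> 40 at the corner: threshold lands at the corner value
  expect_lt(abs(f$threshold_mV + 60), 0.5)
  amp <- f$amplitude_mV
  width_analytic <- (amp / 2) / a + (amp / 2) / b
  expect_equal(f$fwhm_ms, width_analytic, tolerance = 0.02)
  expect_equal(f$ahp_amplitude_mV, -60 - (-70), tolerance = 0.5)
})

test_that("generator parameters are recovered within 2 percent", {
  grid <- expand.grid(thr = c(-45, -40), amp = c(70, 90),
                      R = c(100, 160))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sw <- simulate_sweeps(R_MOhm = g$R, threshold_mV = g$thr,
                          amplitude_mV = g$amp, ahp_mV = 10, fwhm_ms = 1,
                          rheobase_pA = 100, fi_gain = 0.04)
    k <- match(250, sw$currents_pA)
    f <- detect_spikes_and_features(sw$traces[, k], sw$dt)
    expect_gt(nrow(f), 0)
    expect_lt(abs(mean(f$threshold_mV) - g$thr) / abs(g$thr), 0.02)
    expect_lt(abs(mean(f$amplitude_mV) - g$amp) / g$amp, 0.02)
    expect_lt(abs(mean(f$fwhm_ms) - 1), 0.05)
    expect_lt(abs(input_resistance(sw) - g$R) / g$R, 0.02)
  }
})

test_that("input resistance follows Ohm's law on idealized deflections", {
  mk <- function(dv) {
    t <- seq(0, 0.7 - 1e-4, by = 1e-4)
    v <- ifelse(t >= 0.1 & t < 0.6, -70 + dv, -70)
    sweep_set(t, matrix(v, ncol = 1), -100, 0.1, 0.6)
  }
  expect_equal(input_resistance(mk(-10)), 100)
  expect_equal(input_resistance(mk(-5)), 50)
  expect_error(input_resistance(sweep_set(c(0, 1e-4),
                                          matrix(-70, 2, 1), 50, 0, 1e-4)),
               "-100 pA")
})

test_that("F-I curves are monotone and burst doublets are scored", {
  sw <- simulate_sweeps(fi_gain = 0.04, seed = 2)
  fi <- fi_and_burst_curves(sw)
  expect_equal(fi$current_pA, seq(-300, 400, by = 50))
  expect_true(all(diff(fi$rate_hz) >= 0))
  expect_equal(fi$rate_hz[fi$current_pA < 100], rep(0, 8))
  expect_equal(fi$n_spikes[fi$current_pA == 250], 6)
  expect_equal(fi$rate_hz[fi$current_pA == 250], 12)   # n / 0.5 s
  # zero gain -> no APs at any current
  fi0 <- fi_and_burst_curves(simulate_sweeps(fi_gain = 0))
  expect_true(all(fi0$n_spikes == 0))
  expect_true(all(fi0$burst_proportion == 0))
  # bursty generator produces nonzero burst proportions at high currents
  swb <- simulate_sweeps(fi_gain = 0.04, burstiness = 0.8, seed = 3)
  fib <- fi_and_burst_curves(swb)
  expect_gt(max(fib$burst_proportion), 50)
})

test_that("feature extraction is invariant to a DC offset", {
  sw <- simulate_sweeps()
  k <- match(300, sw$currents_pA)
  f0 <- detect_spikes_and_features(sw$traces[, k], sw$dt)
  f5 <- detect_spikes_and_features(sw$traces[, k] + 5, sw$dt)
  expect_equal(f5$threshold_mV, f0$threshold_mV + 5, tolerance = 1e-6)
  expect_equal(f5$amplitude_mV, f0$amplitude_mV, tolerance = 1e-6)
  expect_equal(f5$fwhm_ms, f0$fwhm_ms, tolerance = 1e-6)
  expect_equal(f5$ahp_amplitude_mV, f0$ahp_amplitude_mV, tolerance = 1e-6)
  # subthreshold sweeps hold no APs
  expect_equal(nrow(detect_spikes_and_features(sw$traces[, 1], sw$dt)), 0)
  expect_error(detect_spikes_and_features(sw$traces[, 1], dt = 1e-3), "dt")
})

test_that("sweep sets round-trip through the tabular CSV dialect", {
  sw <- simulate_sweeps(currents_pA = c(-100, 0, 200), dt = 1e-4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps_csv(sw, path)
  sw2 <- read_sweeps_csv(path, sw$onset_s, sw$offset_s)
  expect_equal(sw2$currents_pA, sw$currents_pA)
  expect_equal(sw2$traces, sw$traces, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(input_resistance(sw2), input_resistance(sw),
               tolerance = 1e-6)
})
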