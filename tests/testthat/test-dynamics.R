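test_that("sliding windows give 1800 truncated bins for a 30-min epoch", {
  sp <- seq(0.25, 1800, by = 0.5)  # 2 Hz regular train
  ir <- instantaneous_rates(sp, c(0, 1800))
  expect_length(ir$values, 1800)
  expect_equal(ir$values[1:1700], rep(2, 1700), tolerance = 1e-9)
  # final window [1799, 1800) is 1 s long: rate = count in it
  sp2 <- c(10, 1799.1, 1799.5, 1799.9)
  ir2 <- instantaneous_rates(sp2, c(0, 1800))
  expect_equal(ir2$values[1800], 3)
  # penultimate window [1798, 1800) is 2 s long
  expect_equal(ir2$values[1799], 3 / 2)
  expect_error(instantaneous_rates(sp, c(0, 1800), window_s = 0), "window_s")
  expect_error(instantaneous_rates(sp, c(0, 1800.5)), "multiple")
})

test_that("dynamics summaries match hand-computed statistics", {
  series <- structure(list(values = c(1, 1, 3), starts = 0:2, window_s = 3,
                           step_s = 1), class = "instant_rate_series")
  s <- summarize_dynamics(series)
  expect_equal(s$fr_range, 2)
  expect_equal(s$sigma, sqrt(4 / 3))  # sample SD of (1, 1, 3) = 1.1547
  expect_equal(s$sigma, 1.1547, tolerance = 1e-4)
  s0 <- summarize_dynamics(structure(list(values = rep(2, 10), starts = 0:9),
                                     class = "instant_rate_series"))
  expect_equal(s0$sigma, 0)
  expect_equal(s0$fr_range, 0)
})

test_that("sigma and range equal a brute-force recomputation exactly", {
  set.seed(3)
  sp <- sort(runif(3000, 0, 1800))
  ir <- instantaneous_rates(sp, c(0, 1800))
  brute <- vapply(0:1799, function(k) {
    e <- min(k + 3, 1800)
    sum(sp >= k & sp < e) / (e - k)
  }, 0)
  expect_identical(ir$values, brute)
  s <- summarize_dynamics(ir)
  expect_identical(s$sigma, sd(brute))
  expect_identical(s$fr_range, max(brute) - min(brute))
  # sigma is invariant to a time shift of the whole train
  ir_shift <- instantaneous_rates(sp + 300, c(300, 2100))
  expect_equal(summarize_dynamics(ir_shift)$sigma, s$sigma)
})

test_that("Poisson trains have sigma near sqrt(rate/window)", {
  set.seed(9)
  for (rate in c(2, 8)) {
    sp <- cumsum(rexp(rate * 2200, rate))
    sp <- sp[sp < 1800]
    s <- summarize_dynamics(instantaneous_rates(sp, c(0, 1800)))
    expect_lt(abs(s$sigma - sqrt(rate / 3)) / sqrt(rate / 3), 0.12)
  }
})

test_that("normalized rate histograms place values by decile", {
  expect_equal(normalized_rate_histogram(c(0, 5, 10)),
               c(1, 0, 0, 0, 0, 1, 0, 0, 0, 1) / 3)
  h <- normalized_rate_histogram(rep(4, 7))
  expect_equal(h, c(rep(0, 9), 1))       # constant series: all mass on top
  set.seed(4)
  hr <- normalized_rate_histogram(runif(500))
  expect_equal(sum(hr), 1)
  expect_error(normalized_rate_histogram(rep(0, 5)), "all-zero")
})

test_that("per-session statistics use the windows inside each session", {
  sp <- c(seq(300.25, 899.8, by = 0.5), seq(900.1, 1499.9, by = 0.1))
  ir <- instantaneous_rates(sp, c(300, 2100))
  bounds <- data.frame(epoch = c("EE", "SO1", "SO2"),
                       start = c(300, 900, 1500), end = c(900, 1500, 2100))
  s <- summarize_dynamics(ir, bounds)
  expect_equal(nrow(s$per_session), 3)
  expect_gt(s$per_session$mean_rate[2], s$per_session$mean_rate[1])
  expect_equal(s$per_session$mean_rate[3], 0)
})

test_that("maximum delta firing rate follows its zone definitions", {
  iv1 <- iv(0, 10); iv2 <- iv(20, 30); ivc <- iv(40, 50)
  sp <- c(runif(20, 0, 10), runif(50, 20, 30), runif(30, 40, 50))
  r <- max_delta_fr(sort(sp), iv1, iv2, ivc)
  expect_equal(r$fr_i1, 2); expect_equal(r$fr_i2, 5); expect_equal(r$fr_c, 3)
  expect_equal(r$max_delta, 2)
  expect_equal(r$normalized_max_delta, 0.25)  # max(1/5, 2/8)
  # all three equal -> both zero
  sp_eq <- c(1, 21, 41)
  r0 <- max_delta_fr(sp_eq, iv1, iv2, ivc)
  expect_equal(r0$max_delta, 0)
  expect_equal(r0$normalized_max_delta, 0)
  # an empty zone rate against a firing center gives the normalized maximum 1
  r1 <- max_delta_fr(c(41, 42), iv1, iv2, ivc)
  expect_equal(r1$normalized_max_delta, 1)
  expect_error(max_delta_fr(sp_eq, interval_set(), iv2, ivc), "zero")
})

test_that("sigma-vs-mean regression detects a scaled-down sigma group", {
  set.seed(12)
  n <- 60
  mean_rate <- 10^runif(2 * n, -0.3, 1.2)
  sigma_wt <- 10^(0.5 * log10(mean_rate[1:n]) + 0.1 +
                    rnorm(n, 0, 0.05))
  sigma_ko <- 10^(0.5 * log10(mean_rate[(n + 1):(2 * n)]) + 0.1 +
                    rnorm(n, 0, 0.05)) * 0.7
  units <- data.frame(mean_rate = mean_rate,
                      sigma = c(sigma_wt, sigma_ko),
                      group = rep(c("WT", "KO"), each = n))
  r <- sigma_vs_mean_regression(units)
  cmp <- r$comparison
  expect_gt(cmp$p_slope, 0.05)           # equal slopes by construction
  expect_lt(cmp$p_intercept, 0.001)      # x0.7 sigma -> lower elevation
  # group order in split() is alphabetical: KO first
  expect_lt(cmp$intercept1, cmp$intercept2)
  expect_equal(cmp$intercept2 - cmp$intercept1, -log10(0.7),
               tolerance = 0.05)
  # nonpositive units are dropped with a warning
  units$sigma[1] <- 0
  expect_warning(sigma_vs_mean_regression(units), "dropped")
})
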