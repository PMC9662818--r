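test_that("binned rates partition intervals and drop the remainder", {
  # one 2.2 s interval -> 4 bins of 0.5 s, trailing 0.2 s discarded
  expect_length(binned_rates(numeric(0), iv(0, 2.2)), 4)
  # 4 spikes inside one 0.5 s bin -> 8 Hz
  expect_equal(binned_rates(c(0.1, 0.2, 0.3, 0.4), iv(0, 0.5)), 8)
  expect_equal(binned_rates(numeric(0), iv(c(0, 10), c(1, 11))),
               rep(0, 4))
  expect_length(binned_rates(1:3, interval_set()), 0)
  # bin membership is half-open: a spike at the bin edge joins the next bin
  expect_equal(binned_rates(0.5, iv(0, 1)), c(0, 2))
})

test_that("threshold-sweep auROC matches the rank-statistic oracle", {
  expect_equal(auroc(rep(2, 10), rep(1, 10)), 1.0)
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # frozen rank oracle: exhaustive pairwise P(a>b) + 0.5 P(a=b) = 0.28125
  expect_equal(rank_auc(c(0, 1, 2, 3), c(1, 2, 3, 4)), 0.28125)
  expect_lt(abs(auroc(c(0, 1, 2, 3), c(1, 2, 3, 4)) - 0.28125), 0.01)
  expect_error(auroc(numeric(0), 1:3), "empty")
})

test_that("auROC is symmetric and agrees with the rank oracle", {
  # well-conditioned continuous data: equal-scale normal location shifts
  set.seed(7)
  for (r in 1:200) {
    a <- rnorm(sample(20:80, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(20:80, 1))
    expect_lt(abs(auroc(a, b) + auroc(b, a) - 1), 0.021)
    expect_lt(abs(auroc(a, b) - rank_auc(a, b)), 0.01)
  }
})

test_that("auROC is invariant to increasing transforms of both samples", {
  set.seed(8)
  for (r in 1:100) {
    a <- rnorm(sample(40:100, 1), mean = runif(1, -0.5, 0.5), sd = 0.5)
    b <- rnorm(sample(40:100, 1), sd = 0.5)
    base <- auroc(a, b)
    # positive affine maps carry the threshold grid along: exact
    expect_equal(auroc(2.5 * a + 7, 2.5 * b + 7), base, tolerance = 1e-3)
    # nonlinear monotone maps re-space the grid: within discretization
    expect_lt(abs(auroc(exp(a), exp(b)) - base), 0.02)
  }
})

test_that("target-neuron calls respond to separation and data sufficiency", {
  set.seed(11)
  # 10 Hz sniffing vs 1 Hz center, 60 bins each: responsive increasing
  sniff <- iv(seq(0, by = 2, length.out = 30),
              seq(1, by = 2, length.out = 30))
  center <- iv(seq(100, by = 2, length.out = 30),
               seq(101, by = 2, length.out = 30))
  spikes <- sort(c(runif(600, 0, 60), runif(60, 100, 160)))
  res <- classify_target_neuron(spikes, sniff, center, seed = 3)
  expect_equal(res$label, "responsive")
  expect_equal(res$direction, "increasing")
  expect_gt(res$auroc, res$q_hi)
  # decreasing direction for suppressed firing
  res_dec <- classify_target_neuron(spikes, center, sniff, seed = 4)
  expect_equal(res_dec$direction, "decreasing")
  # fewer than 40 bins in either context -> insufficient data
  res39 <- classify_target_neuron(spikes, sniff,
                                  iv(100, 119.8), seed = 5)
  expect_equal(res39$n_center_bins, 39)
  expect_equal(res39$label, "insufficient_data")
  expect_error(classify_target_neuron(spikes, sniff, center,
                                      n_shuffles = 0), "n_shuffles")
})

test_that("spike density functions bin, average and normalize correctly", {
  # one trial, one spike at +0.1 s: the [0, 0.25) bin reads 4 Hz
  s <- spike_density_function(10.1, onsets = 10)
  expect_length(s, 18)
  expect_equal(s[7], 4)
  expect_equal(sum(s), 4)
  # averaging two identical trials changes nothing
  s2 <- spike_density_function(c(10.1, 110.1), onsets = c(10, 110))
  expect_equal(s2, s)
  # joint normalization: the unit's maximum across targets becomes 1
  sdfs <- normalize_sdfs(list(empty = s, social = 2 * s, object = s / 2))
  expect_equal(max(unlist(sdfs)), 1)
  expect_equal(max(sdfs$social), 1)
  expect_equal(max(sdfs$empty), 0.5)
  expect_error(spike_density_function(1, numeric(0)), "onset")
})

test_that("z-scores and trial consistency follow their definitions", {
  st <- list(mu_c = 3, sigma_c = 1, n_bins = 100)
  # FR_T = 5 Hz over a 2 s interval with 10 spikes
  expect_equal(target_zscore(seq(0, 1.8, by = 0.2), iv(0, 2), st), 2)
  expect_equal(target_zscore(c(0.1, 0.5, 0.9, 1.3, 1.7, 1.9), iv(0, 2), st),
               0)
  expect_equal(target_zscore(c(0.5, 1.5), iv(0, 2),
                             list(mu_c = 3, sigma_c = 2)), -1)
  expect_error(target_zscore(1:3, iv(0, 2), list(mu_c = 1, sigma_c = 0)),
               "degenerate")
  expect_equal(per_trial_zscores(c(0.25, 0.75, 10.25), iv(c(0, 10), c(1, 11)),
                                 st), c(-1, -2))
  expect_equal(trial_consistency(c(0.5, -0.2, 1.1, 0.3), "increasing"), 75)
  expect_equal(trial_consistency(c(1, 2, 3), "increasing"), 100)
  expect_equal(trial_consistency(c(-1, -1), "decreasing"), 100)
  expect_equal(trial_consistency(c(0, 1), "increasing"), 50)  # zero counts against
  expect_error(trial_consistency(numeric(0), "increasing"), "trials")
})

test_that("modulated synthetic units are recovered with their direction", {
  b <- small_bundle()
  ev <- small_events()
  pooled <- pool_target_events(ev)
  gains <- vapply(b$truth, function(s) s$target_gains[["social"]], 0)
  res <- classify_all_units(b, ev, n_shuffles = 400)
  soc <- res[res$target == "social", ]
  mod <- soc[match(names(gains)[gains > 1], soc$unit_id), ]
  expect_true(all(mod$label == "responsive"))
  expect_true(all(mod$direction == "increasing"))
  # increasing units have positive mean per-trial z-scores
  for (id in mod$unit_id) {
    u <- b$units[[match(id, vapply(b$units, `[[`, "", "unit_id"))]]
    cs <- center_stats(u$spikes, pooled$center)
    z <- per_trial_zscores(u$spikes, pooled$sniff$social, cs)
    expect_gt(mean(z), 0)
  }
  # cross-session consistency: first vs second S-O z-scores correlate
  zs <- sapply(c("SO1.social", "SO2.social"), function(k)
    vapply(b$units, function(u)
      target_zscore(u$spikes, ev$sniff[[k]],
                    center_stats(u$spikes, pooled$center)), 0))
  expect_gt(cor(zs[, 1], zs[, 2]), 0.5)
})
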