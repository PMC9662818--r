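# shared fixtures, built in code and memoized per test run

iv <- function(start, end, label = NA_character_, session = NA_character_) {
  interval_set(start, end, label = label, session = session)
}

.fixture_env <- new.env(parent = emptyenv())

# small synthetic experiment reused across test files
small_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- simulate_experiment(
      sim_config(n_units = 8, social_neuron_fraction = 0.5,
                 increasing_fraction = 1), seed = 101)
  .fixture_env$bundle
}

small_events <- function() {
  if (is.null(.fixture_env$events))
    .fixture_env$events <- detect_events(small_bundle()$tracking,
                                         small_bundle()$targets)
  .fixture_env$events
}

# stationary tracking series: every part at a fixed point
fixed_track <- function(nose_x, n_frames = 120, fps = 30, nose_y = 5,
                        tail_dx = 4, session = "EE", t0 = 0) {
  mk <- function(x, y) data.frame(x = rep(x, n_frames), y = rep(y, n_frames),
                                  likelihood = 1)
  tracking_series(t0 + (seq_len(n_frames) - 1) / fps,
                  list(nose = mk(nose_x, nose_y),
                       tail_base = mk(nose_x + tail_dx, nose_y)),
                  fps, session = session)
}

# rank-statistic AUC with ties counted one half (independent oracle)
rank_auc <- function(a, b) {
  r <- rank(c(a, b))
  (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
    (length(a) * length(b))
}
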