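test_that("sniff-zone membership follows the 3-cm nose rule", {
  # nose fixed at 1 cm for 120 frames @30 fps -> one 4.0 s left sniff bout
  out <- compute_zone_intervals(fixed_track(1), kind = "sniff",
                                side = "left")
  expect_equal(nrow(out), 1)
  expect_equal(out$end - out$start, 4.0)
  # nose at 4 cm: outside the 3-cm band
  expect_equal(nrow(compute_zone_intervals(fixed_track(4), kind = "sniff",
                                           side = "left")), 0)
  # right-face symmetry
  out_r <- compute_zone_intervals(fixed_track(43), kind = "sniff",
                                  side = "right")
  expect_equal(interval_duration(out_r), 4.0)
})

test_that("in-zone and center membership use the nose/tail midpoint", {
  # nose 18, tail 22 -> body center 20: center-zone member ([18, 27))
  expect_equal(interval_duration(compute_zone_intervals(
    fixed_track(18), kind = "center")), 4.0)
  # body center 8 -> left in-zone (within 9 cm)
  expect_equal(interval_duration(compute_zone_intervals(
    fixed_track(6), kind = "inzone", side = "left")), 4.0)
  expect_equal(nrow(compute_zone_intervals(
    fixed_track(6), kind = "center")), 0)
  # missing part fails by name
  tr <- fixed_track(6)
  tr$parts$tail_base <- NULL
  expect_error(compute_zone_intervals(tr, kind = "inzone", side = "left"),
               "tail_base")
})

test_that("valid-trial filtering drops short trials then short gaps", {
  f <- function(s, e, d, g) as.data.frame(
    filter_valid_intervals(iv(s, e), d, g))[, c("start", "end")]
  expect_equal(f(c(0, 2), c(1.5, 3.5), 1, 2),
               data.frame(start = 0, end = 1.5))
  expect_equal(f(c(0, 5), c(0.8, 7), 1, 2),
               data.frame(start = 5, end = 7))
  expect_equal(f(c(0, 3.1), c(1, 4.2), 1, 2),
               data.frame(start = c(0, 3.1), end = c(1, 4.2)))
  expect_error(filter_valid_intervals(iv(0, 1), -1, 0), "non-negative")
})

test_that("valid-trial filtering is idempotent on random interval sets", {
  set.seed(31)
  for (r in 1:50) {
    n <- sample(1:20, 1)
    gaps <- runif(n, 0, 3)
    durs <- runif(n, 0.1, 3)
    ends <- cumsum(gaps + durs)
    starts <- ends - durs
    x <- filter_valid_intervals(iv(starts, ends), 1, 2)
    expect_identical(filter_valid_intervals(x, 1, 2), x)
    if (nrow(x)) {
      expect_true(all(x$end - x$start >= 1))
      if (nrow(x) > 1)
        expect_true(all(x$start[-1] - x$end[-nrow(x)] >= 2))
    }
  }
})

test_that("proximity classification splits at 2.5 and 10 cm", {
  n <- 90  # 3 s at 30 fps
  sub <- fixed_track(1, n_frames = n)
  make_target <- function(d) {
    tr <- sub
    tr$parts$target_nose <- data.frame(x = rep(1, n), y = rep(5 + d, n),
                                       likelihood = 1)
    tr
  }
  p <- compute_proximity_intervals(sub, "social", make_target(2))
  expect_equal(interval_duration(p$proximal), 3)
  expect_equal(nrow(p$distal), 0)
  p5 <- compute_proximity_intervals(sub, "social", make_target(5))
  expect_equal(nrow(p5$proximal), 0)
  expect_equal(interval_duration(p5$distal), 3)
  p12 <- compute_proximity_intervals(sub, "social", make_target(12))
  expect_equal(nrow(p12$proximal) + nrow(p12$distal), 0)
  # object distance is measured to the face center point
  po <- compute_proximity_intervals(fixed_track(2, nose_y = 5), "object",
                                    "left")
  expect_equal(interval_duration(po$proximal), 4)
  # distance profile accounts for every frame
  expect_equal(sum(p$distance_profile$duration_s), n / 30)
})

test_that("distance moved sums body-center displacements", {
  mk <- function(xs, ys) tracking_series(
    (seq_along(xs) - 1) / 30,
    list(nose = data.frame(x = xs, y = ys, likelihood = 1),
         tail_base = data.frame(x = xs, y = ys, likelihood = 1)), 30)
  expect_equal(distance_moved(mk(seq(0, 10, length.out = 50), rep(5, 50))),
               10)
  expect_equal(distance_moved(mk(rep(3, 10), rep(5, 10))), 0)
  # L-shaped path: 3 cm in x then 4 cm in y
  expect_equal(distance_moved(mk(c(0, 3, 3), c(0, 0, 4))), 7)
})

test_that("zone sets nest and durations stay within the session", {
  b <- small_bundle()
  ev <- small_events()
  geom <- zone_geometry()
  for (ses in names(b$tracking)) {
    tr <- b$tracking[[ses]]
    dur <- b$layout$session_durations[[ses]]
    for (side in c("left", "right")) {
      sn <- compute_zone_intervals(tr, geom, "sniff", side)
      iz <- compute_zone_intervals(tr, geom, "inzone", side)
      expect_lte(interval_duration(sn), dur + 1 / tr$fps)
      # every sniff second is covered by the same-side in-zone set
      mid <- (sn$start + sn$end) / 2
      covered <- vapply(mid, function(m)
        any(m >= iz$start & m < iz$end), logical(1))
      expect_true(all(covered))
    }
    cz <- compute_zone_intervals(tr, geom, "center")
    izl <- compute_zone_intervals(tr, geom, "inzone", "left")
    # center and in-zone are disjoint
    midc <- (cz$start + cz$end) / 2
    expect_false(any(vapply(midc, function(m)
      any(m >= izl$start & m < izl$end), logical(1))))
  }
})

test_that("low-likelihood frames are carried forward before zoning", {
  tr <- fixed_track(1, n_frames = 60)
  tr$parts$nose$x[31:60] <- 40
  tr$parts$nose$likelihood[31:60] <- 0.2  # bad tracking: LOCF to x = 1
  out <- compute_zone_intervals(tr, kind = "sniff", side = "left")
  expect_equal(interval_duration(out), 2.0)
  out2 <- compute_zone_intervals(tr, kind = "sniff", side = "left",
                                 min_likelihood = 0.1)
  expect_equal(interval_duration(out2), 1.0)
})
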