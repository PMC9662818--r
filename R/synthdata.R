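#' Specification of one synthetic unit
#'
#' Rates are in Hz; \code{target_gains} multiply the baseline rate while the
#' subject's nose occupies the sniffing zone of the named target (> 1
#' increasing, < 1 decreasing, 1 none). \code{burst_propensity} is the
#' probability that a spike spawns 1-2 extra spikes at
#' \code{intra_burst_isi} spacing.
#'
#' @param genotype \code{"WT"} or \code{"KO"}.
#' @param baseline_rate,rest_rate Hz, non-negative.
#' @param target_gains Named numeric: \code{left_empty}, \code{right_empty},
#'   \code{social}, \code{object}.
#' @param burst_propensity Probability in [0, 1].
#' @param intra_burst_isi Seconds between burst spikes.
#' @param hvw,pvr Waveform half-valley width and peak-to-valley ratio (same
#'   scale as the classification thresholds).
#' @param isolation_distance,l_ratio Cluster-quality metrics.
#' @param is_social_neuron Ground-truth flag.
#' @return Object of class \code{unit_spec}.
#' @export
unit_spec <- function(genotype = "WT", baseline_rate = 3, rest_rate = 3,
                      target_gains = c(left_empty = 1, right_empty = 1,
                                       social = 1, object = 1),
                      burst_propensity = 0.2, intra_burst_isi = 0.005,
                      hvw = 260, pvr = 2, isolation_distance = 40,
                      l_ratio = 0.03, is_social_neuron = FALSE) {
  stopifnot(baseline_rate >= 0, rest_rate >= 0,
            burst_propensity >= 0, burst_propensity <= 1,
            hvw > 0, pvr > 0, intra_burst_isi > 0)
  gains <- c(left_empty = 1, right_empty = 1, social = 1, object = 1)
  gains[names(target_gains)] <- target_gains
  if (any(gains < 0)) stop("target gains must be non-negative")
  structure(list(genotype = genotype, baseline_rate = baseline_rate,
                 rest_rate = rest_rate, target_gains = gains,
                 burst_propensity = burst_propensity,
                 intra_burst_isi = intra_burst_isi, hvw = hvw, pvr = pvr,
                 isolation_distance = isolation_distance, l_ratio = l_ratio,
                 is_social_neuron = is_social_neuron),
            class = "unit_spec")
}

# AR(1) jitter helper, clipped to [lo, hi], centered on `center`
ar1_jitter <- function(n, center, sd, lo, hi, phi = 0.9) {
  e <- stats::rnorm(n, 0, sd)
  x <- stats::filter(e, phi, method = "recursive")
  pmin(pmax(center + as.numeric(x), lo), hi)
}

# One session's trajectory: a bounded walk alternating face dwells (sniffing
# bouts), travels at constant speed, and short center-zone dwells, so that
# both faces and the center zone accrue ample valid trials.
simulate_session_track <- function(layout, session, t0, with_target = FALSE,
                                   target_side = "left") {
  fps <- layout$fps
  L <- layout$chamber_length
  W <- layout$chamber_width
  n <- round(layout$session_durations[[session]] * fps)
  speed <- 15  # cm/s travel speed

  nose_x <- numeric(0); heading <- numeric(0)
  cur <- L / 2
  # state sequence: left dwell -> center -> right dwell -> center -> ...
  plan <- c("left", "center", "right", "center")
  k <- 0
  while (length(nose_x) < n) {
    st <- plan[k %% 4 + 1]; k <- k + 1
    base <- switch(st, left = 1.5, right = L - 1.5, center = L / 2 + 0.5)
    # travel to the new base
    tf <- max(1, round(abs(base - cur) / speed * fps))
    nose_x <- c(nose_x, seq(cur, base, length.out = tf))
    heading <- c(heading, rep(sign(base - cur + 1e-9), tf))
    # dwell
    dur <- switch(st, left = stats::runif(1, 1.5, 4),
                  right = stats::runif(1, 1.5, 4),
                  center = stats::runif(1, 1, 2.5))
    df <- max(1, round(dur * fps))
    jit <- switch(st,
                  left = ar1_jitter(df, 1.5, 0.12, 0.5, 2.5) - 1.5,
                  right = ar1_jitter(df, L - 1.5, 0.12, L - 2.5, L - 0.5) -
                    (L - 1.5),
                  center = ar1_jitter(df, 0, 0.2, -1.5, 1.5))
    nose_x <- c(nose_x, base + jit)
    heading <- c(heading, rep(switch(st, left = -1, right = 1, center = 1), df))
    cur <- base + jit[df]
  }
  nose_x <- pmin(pmax(nose_x[seq_len(n)], 0.3), L - 0.3)
  heading <- heading[seq_len(n)]
  nose_y <- ar1_jitter(n, W / 2, 0.15, 1.5, W - 1.5)

  u <- heading  # x-component of the heading unit vector (y-component 0)
  mk <- function(x, y) data.frame(x = x, y = y, likelihood = 1)
  parts <- list(
    nose = mk(nose_x, nose_y),
    left_ear = mk(pmin(pmax(nose_x - 0.5 * u, 0.1), L - 0.1),
                  pmin(pmax(nose_y + 0.8, 0.1), W - 0.1)),
    right_ear = mk(pmin(pmax(nose_x - 0.5 * u, 0.1), L - 0.1),
                   pmin(pmax(nose_y - 0.8, 0.1), W - 0.1)),
    body_center = mk(pmin(pmax(nose_x - 2 * u, 0.1), L - 0.1), nose_y),
    tail_base = mk(pmin(pmax(nose_x - 4 * u, 0.1), L - 0.1), nose_y))

  if (with_target) {
    face_x <- if (target_side == "left") 0 else L
    tx <- if (target_side == "left") ar1_jitter(n, 0.5, 0.08, 0.1, 0.9)
          else ar1_jitter(n, L - 0.5, 0.08, L - 0.9, L - 0.1)
    # the target mouse tracks the subject's nose height when it is close
    near <- abs(nose_x - face_x) <= 5
    ty <- ifelse(near, 0.85 * nose_y + 0.15 * W / 2, W / 2) +
      stats::rnorm(n, 0, 0.1)
    ty <- pmin(pmax(ty, 0.5), W - 0.5)
    bx <- if (target_side == "left") tx + 2 else tx - 2
    parts$target_nose <- mk(tx, ty)
    parts$target_body_center <- mk(pmin(pmax(bx, 0.1), L - 0.1), ty)
  }

  tracking_series(t0 + (seq_len(n) - 1) / fps, parts, fps, session = session,
                  chamber_length = L, chamber_width = W)
}

# Piecewise-constant rate segments for one unit over the whole experiment:
# rest epoch at rest_rate, sniff-zone occupancy at baseline x gain of the
# occupied target, everything else at baseline.
unit_rate_segments <- function(spec, tracking, targets, layout) {
  ep <- session_epochs(layout)
  segs <- data.frame(start = 0, end = ep$end[ep$epoch == "rest"],
                     rate = spec$rest_rate)
  for (ses in names(tracking)) {
    track <- tracking[[ses]]
    tg <- targets[targets$session == ses, , drop = FALSE]
    zone <- rep("none", length(track$times))
    nose <- track$parts$nose
    gd <- zone_geometry()
    for (i in seq_len(nrow(tg))) {
      member <- if (tg$side[i] == "left") nose$x <= gd$sniff_depth
                else nose$x >= track$chamber_length - gd$sniff_depth
      zone[member] <- tg$target[i]
    }
    r <- rle(zone)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    rate <- ifelse(r$values == "none", spec$baseline_rate,
                   spec$baseline_rate * spec$target_gains[r$values])
    segs <- rbind(segs,
                  data.frame(start = track$times[starts],
                             end = track$times[ends] + 1 / track$fps,
                             rate = as.numeric(rate)))
  }
  segs
}

#' Simulate one unit's spike train
#'
#' Spikes are drawn from an inhomogeneous Poisson process by thinning a
#' homogeneous process at the maximum segment rate; each retained spike then
#' spawns, with probability \code{burst_propensity}, one or two extra spikes
#' at \code{intra_burst_isi} spacing.
#'
#' @param spec A \code{\link{unit_spec}}.
#' @param segments data.frame with columns \code{start}, \code{end},
#'   \code{rate} (Hz) covering the experiment; contiguous segments.
#' @param t_total Total experiment duration (seconds).
#' @param seed Optional integer seed for this unit's stream.
#' @return Sorted numeric spike times in \code{[0, t_total)}.
#' @export
simulate_unit_spikes <- function(spec, segments, t_total, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(segments$rate < 0)) stop("negative rate in segments")
  rmax <- max(segments$rate)
  if (rmax == 0) return(numeric(0))
  n <- stats::rpois(1, rmax * t_total)
  t <- sort(stats::runif(n, 0, t_total))
  seg_idx <- findInterval(t, segments$start)
  rate_t <- segments$rate[seg_idx]
  keep <- stats::runif(n) < rate_t / rmax
  t <- t[keep]
  if (spec$burst_propensity > 0 && length(t)) {
    spawn <- stats::runif(length(t)) < spec$burst_propensity
    extra <- numeric(0)
    if (any(spawn)) {
      k <- sample(1:2, sum(spawn), replace = TRUE)
      base <- t[spawn]
      extra <- c(base + spec$intra_burst_isi,
                 base[k == 2] + 2 * spec$intra_burst_isi)
    }
    t <- sort(c(t, extra))
  }
  t[t < t_total]
}

# Draw the per-unit specs implied by the generator configuration.
draw_unit_specs <- function(config) {
  n <- config$n_units
  genotypes <- rep_len(config$genotypes, n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genotypes[i]
    ko <- identical(g, "KO")
    # KO preset: resting rate up ~30%, burst propensity down ~50%,
    # social-modulated fraction down ~40% relative to WT
    frac <- config$social_neuron_fraction * (if (ko) 0.6 else 1)
    base <- exp(stats::rnorm(1, log(config$baseline_rate_mean), 0.35))
    rest <- base * (if (ko) 1.3 else 1)
    is_soc <- stats::runif(1) < frac
    gains <- c(left_empty = 1, right_empty = 1, social = 1, object = 1)
    if (is_soc) {
      increasing <- stats::runif(1) < config$increasing_fraction
      gains["social"] <- if (increasing) config$social_gain
                         else 1 / config$social_gain
    }
    is_pexc <- stats::runif(1) < config$pexc_fraction
    specs[[i]] <- unit_spec(
      genotype = g, baseline_rate = base, rest_rate = rest,
      target_gains = gains,
      burst_propensity = (if (ko) 0.5 else 1) * config$burst_propensity,
      hvw = if (is_pexc) stats::rnorm(1, 260, 20) else stats::rnorm(1, 150, 15),
      pvr = if (is_pexc) stats::rnorm(1, 2, 0.2) else stats::rnorm(1, 1.1, 0.1),
      isolation_distance = stats::runif(1, 30, 60),
      l_ratio = stats::runif(1, 0.01, 0.08),
      is_social_neuron = is_soc)
  }
  specs
}

#' Generator settings
#'
#' @param n_units Number of units to simulate.
#' @param genotypes Genotype per unit, recycled (\code{"WT"}, \code{"KO"}).
#' @param social_neuron_fraction Fraction of units given a social-zone gain
#'   (the KO preset reduces it by 40\%).
#' @param social_gain Multiplicative sniff-zone gain of social neurons
#'   (increasing units; decreasing units get its reciprocal).
#' @param increasing_fraction Fraction of social neurons that increase.
#' @param baseline_rate_mean Geometric-mean baseline rate (Hz).
#' @param burst_propensity WT burst-spawn probability (KO preset halves it).
#' @param pexc_fraction Fraction of units drawn with pExc-like waveforms.
#' @param layout A \code{\link{session_layout}}.
#' @return Named list of settings.
#' @export
sim_config <- function(n_units = 100, genotypes = "WT",
                       social_neuron_fraction = 0.2, social_gain = 3,
                       increasing_fraction = 0.7, baseline_rate_mean = 3,
                       burst_propensity = 0.2, pexc_fraction = 0.95,
                       layout = session_layout()) {
  stopifnot(n_units >= 1, social_neuron_fraction >= 0,
            social_neuron_fraction <= 1, social_gain > 0)
  list(n_units = n_units, genotypes = genotypes,
       social_neuron_fraction = social_neuron_fraction,
       social_gain = social_gain, increasing_fraction = increasing_fraction,
       baseline_rate_mean = baseline_rate_mean,
       burst_propensity = burst_propensity, pexc_fraction = pexc_fraction,
       layout = layout)
}

#' Simulate a complete synthetic experiment
#'
#' Generates session trajectories (a bounded walk dwelling at the chamber
#' faces so every target accrues at least 20 s of valid sniffing), per-unit
#' spike trains from an inhomogeneous renewal process with sniff-zone gains
#' and burst insertion, unit metadata, and ground truth. Identical
#' \code{(config, seed)} gives an identical bundle.
#'
#' @param config A \code{\link{sim_config}} list.
#' @param seed Integer seed.
#' @param max_redraws Trajectory redraw attempts before failing.
#' @return Object of class \code{experiment_bundle}: \code{layout},
#'   \code{tracking} (per session), \code{targets} (side-to-target map),
#'   \code{units} (list with \code{unit_id}, \code{spikes}, waveform and
#'   quality metadata), \code{truth} (per-unit \code{unit_spec}s),
#'   \code{seed}.
#' @export
simulate_experiment <- function(config = sim_config(), seed,
                                max_redraws = 5) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  layout <- config$layout
  ep <- session_epochs(layout)
  sessions <- ep$epoch[ep$epoch != "rest"]

  social_side <- sample(c("left", "right"), 1)
  other <- setdiff(c("left", "right"), social_side)
  targets <- data.frame(
    session = c("EE", "EE", "SO1", "SO1", "SO2", "SO2"),
    side = c("left", "right", social_side, other, other, social_side),
    target = c("left_empty", "right_empty", "social", "object",
               "social", "object"),
    stringsAsFactors = FALSE)

  geom <- zone_geometry()
  d <- lc_defaults()
  for (attempt in seq_len(max_redraws)) {
    tracking <- list()
    for (ses in sessions) {
      t0 <- ep$start[ep$epoch == ses]
      soc_side <- targets$side[targets$session == ses &
                                 targets$target == "social"]
      tracking[[ses]] <- simulate_session_track(
        layout, ses, t0, with_target = length(soc_side) > 0,
        target_side = if (length(soc_side)) soc_side else "left")
    }
    # every one of the six targets needs >= 20 s of valid sniffing
    ok <- TRUE; bad <- NULL
    for (i in seq_len(nrow(targets))) {
      iv <- compute_zone_intervals(tracking[[targets$session[i]]], geom,
                                   "sniff", targets$side[i])
      iv <- filter_valid_intervals(iv, d$sniff_min_duration_s,
                                   d$sniff_min_gap_s)
      if (interval_duration(iv) < 20) {
        ok <- FALSE
        bad <- paste(targets$session[i], targets$target[i], sep = ".")
        break
      }
    }
    if (ok) break
    if (attempt == max_redraws)
      stop("could not satisfy sniffing occupancy for target ", bad)
  }

  specs <- draw_unit_specs(config)
  t_total <- max(ep$end)
  units <- vector("list", config$n_units)
  for (i in seq_len(config$n_units)) {
    segs <- unit_rate_segments(specs[[i]], tracking, targets, layout)
    unit_seed <- (seed %% 100000L) * 10000L + i
    spikes <- simulate_unit_spikes(specs[[i]], segs, t_total,
                                   seed = unit_seed)
    units[[i]] <- list(unit_id = sprintf("unit_%04d", i), spikes = spikes,
                       hvw = specs[[i]]$hvw, pvr = specs[[i]]$pvr,
                       isolation_distance = specs[[i]]$isolation_distance,
                       l_ratio = specs[[i]]$l_ratio,
                       genotype = specs[[i]]$genotype)
  }
  names(specs) <- vapply(units, `[[`, "", "unit_id")
  structure(list(layout = layout, tracking = tracking, targets = targets,
                 units = units, truth = specs, seed = seed, config = config),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("<experiment_bundle>", length(x$units), "units,",
      length(x$tracking), "sessions, seed", x$seed, "\n")
  invisible(x)
}

#' Write an experiment bundle to disk
#'
#' Emits one DeepLabCut-style tracking CSV per session, one spike-time CSV
#' per unit (single column \code{spike_time_s}), a units metadata TSV
#' (\code{unit_id}, \code{hvw}, \code{pvr}, \code{isolation_distance},
#' \code{l_ratio}), a ground-truth TSV, and a JSON layout/config file.
#'
#' @param bundle An \code{\link{experiment_bundle}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  lay <- bundle$layout
  meta <- list(rest_duration = lay$rest_duration,
               session_durations = as.list(lay$session_durations),
               fps = lay$fps, chamber_length = lay$chamber_length,
               chamber_width = lay$chamber_width, seed = bundle$seed,
               targets = bundle$targets)
  jsonlite::write_json(meta, file.path(dir, "layout.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ses in names(bundle$tracking))
    write_tracking_csv(bundle$tracking[[ses]],
                       file.path(dir, paste0("tracking_", ses, ".csv")))
  spike_dir <- file.path(dir, "spikes")
  dir.create(spike_dir, showWarnings = FALSE)
  for (u in bundle$units) {
    df <- data.frame(spike_time_s = u$spikes)
    utils::write.csv(format(df, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     file.path(spike_dir, paste0(u$unit_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  units_df <- do.call(rbind, lapply(bundle$units, function(u)
    data.frame(unit_id = u$unit_id, hvw = u$hvw, pvr = u$pvr,
               isolation_distance = u$isolation_distance,
               l_ratio = u$l_ratio, genotype = u$genotype)))
  utils::write.table(units_df, file.path(dir, "units.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth_df <- do.call(rbind, lapply(names(bundle$truth), function(id) {
    s <- bundle$truth[[id]]
    data.frame(unit_id = id, genotype = s$genotype,
               baseline_rate = s$baseline_rate, rest_rate = s$rest_rate,
               gain_left_empty = s$target_gains[["left_empty"]],
               gain_right_empty = s$target_gains[["right_empty"]],
               gain_social = s$target_gains[["social"]],
               gain_object = s$target_gains[["object"]],
               burst_propensity = s$burst_propensity,
               intra_burst_isi = s$intra_burst_isi,
               is_social_neuron = s$is_social_neuron)
  }))
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an experiment bundle written by \code{\link{write_experiment}}
#'
#' @param dir Directory containing the file set.
#' @return An \code{\link{experiment_bundle}} (without the generator config).
#' @export
read_experiment <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "layout.json"),
                              simplifyVector = TRUE)
  layout <- session_layout(meta$rest_duration,
                           unlist(meta$session_durations), meta$fps,
                           meta$chamber_length, meta$chamber_width)
  ep <- session_epochs(layout)
  tracking <- list()
  for (ses in ep$epoch[ep$epoch != "rest"]) {
    f <- file.path(dir, paste0("tracking_", ses, ".csv"))
    if (file.exists(f))
      tracking[[ses]] <- read_tracking_csv(
        f, layout$fps, t0 = ep$start[ep$epoch == ses], session = ses,
        chamber_length = layout$chamber_length,
        chamber_width = layout$chamber_width)
  }
  units_df <- utils::read.delim(file.path(dir, "units.tsv"))
  units <- lapply(seq_len(nrow(units_df)), function(i) {
    sf <- file.path(dir, "spikes", paste0(units_df$unit_id[i], ".csv"))
    sp <- utils::read.csv(sf)$spike_time_s
    list(unit_id = units_df$unit_id[i],
         spikes = if (length(sp)) as.numeric(sp) else numeric(0),
         hvw = units_df$hvw[i], pvr = units_df$pvr[i],
         isolation_distance = units_df$isolation_distance[i],
         l_ratio = units_df$l_ratio[i],
         genotype = if ("genotype" %in% names(units_df))
           units_df$genotype[i] else NA_character_)
  })
  truth <- NULL
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) {
    td <- utils::read.delim(tf)
    truth <- lapply(seq_len(nrow(td)), function(i)
      unit_spec(genotype = td$genotype[i],
                baseline_rate = td$baseline_rate[i],
                rest_rate = td$rest_rate[i],
                target_gains = c(left_empty = td$gain_left_empty[i],
                                 right_empty = td$gain_right_empty[i],
                                 social = td$gain_social[i],
                                 object = td$gain_object[i]),
                burst_propensity = td$burst_propensity[i],
                intra_burst_isi = td$intra_burst_isi[i],
                is_social_neuron = td$is_social_neuron[i]))
    names(truth) <- td$unit_id
  }
  structure(list(layout = layout, tracking = tracking,
                 targets = as.data.frame(meta$targets), units = units,
                 truth = truth, seed = meta$seed, config = NULL),
            class = "experiment_bundle")
}
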