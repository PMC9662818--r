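#' Current-clamp sweep set
#'
#' Membrane-potential traces for a series of 500-ms square current steps
#' (-300 to 400 pA in 50-pA increments by default).
#'
#' @param time_s Sample times (seconds), uniform.
#' @param traces Matrix of membrane potential (mV), one column per current.
#' @param currents_pA Injected currents, strictly increasing.
#' @param onset_s,offset_s Step window (half-open).
#' @return Object of class \code{sweep_set}.
#' @export
sweep_set <- function(time_s, traces, currents_pA, onset_s, offset_s) {
  traces <- as.matrix(traces)
  stopifnot(nrow(traces) == length(time_s),
            ncol(traces) == length(currents_pA),
            all(diff(currents_pA) > 0), offset_s > onset_s)
  structure(list(time_s = time_s, traces = traces,
                 currents_pA = currents_pA, onset_s = onset_s,
                 offset_s = offset_s,
                 dt = time_s[2] - time_s[1]),
            class = "sweep_set")
}

#' Detect action potentials and extract their features
#'
#' Peaks are local maxima above 0 mV. For each peak the AP threshold is the
#' membrane potential at the last upward crossing of dV/dt = 5 mV/ms before
#' the peak (central differences, linearly interpolated); amplitude is peak
#' minus threshold; AHP amplitude is threshold minus the post-spike trough
#' (searched within 20 ms); FWHM is the width at threshold + amplitude/2,
#' interpolated between samples.
#'
#' @param v Membrane potential trace (mV).
#' @param dt Sampling interval (seconds), at most 0.1 ms.
#' @param dvdt_threshold Upstroke criterion (5 mV/ms).
#' @param ahp_window_ms Post-peak trough search window (20 ms).
#' @return data.frame with one row per AP: \code{spike_time_s},
#'   \code{threshold_mV}, \code{amplitude_mV}, \code{ahp_amplitude_mV},
#'   \code{fwhm_ms}.
#' @export
detect_spikes_and_features <- function(v, dt, dvdt_threshold = 5,
                                       ahp_window_ms = 20) {
  if (dt > 1e-4 + 1e-12) stop("dt must be <= 0.1 ms for derivative fidelity")
  n <- length(v)
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt * 1000), NA)  # mV/ms
  peaks <- which(v > 0)
  peaks <- peaks[peaks > 2 & peaks < n - 1]
  peaks <- peaks[v[peaks] >= v[peaks - 1] & v[peaks] > v[peaks + 1]]
  rows <- list()
  for (p in peaks) {
    j <- p - 1
    while (j > 1 && !is.na(dvdt[j]) && dvdt[j] >= dvdt_threshold) j <- j - 1
    if (j <= 1 || is.na(dvdt[j]) || dvdt[j] >= dvdt_threshold ||
        is.na(dvdt[j + 1]) || dvdt[j + 1] < dvdt_threshold) {
      warning("AP at sample ", p, " discarded: no dV/dt crossing found")
      next
    }
    frac <- (dvdt_threshold - dvdt[j]) / (dvdt[j + 1] - dvdt[j])
    thr <- v[j] + frac * (v[j + 1] - v[j])
    amp <- v[p] - thr
    iw <- min(n, p + round(ahp_window_ms / 1000 / dt))
    trough <- min(v[(p + 1):iw])
    half <- thr + amp / 2
    r <- p
    while (r > 1 && v[r - 1] >= half) r <- r - 1
    t_rise <- if (r == 1) (r - 1) * dt else
      ((r - 1) + (half - v[r - 1]) / (v[r] - v[r - 1]) - 1) * dt
    f <- p
    while (f < n && v[f + 1] >= half) f <- f + 1
    t_fall <- if (f == n) (f - 1) * dt else
      ((f - 1) + (v[f] - half) / (v[f] - v[f + 1])) * dt
    rows[[length(rows) + 1]] <-
      data.frame(spike_time_s = (p - 1) * dt, threshold_mV = thr,
                 amplitude_mV = amp, ahp_amplitude_mV = thr - trough,
                 fwhm_ms = (t_fall - t_rise) * 1000)
  }
  if (!length(rows))
    return(data.frame(spike_time_s = numeric(0), threshold_mV = numeric(0),
                      amplitude_mV = numeric(0),
                      ahp_amplitude_mV = numeric(0), fwhm_ms = numeric(0)))
  do.call(rbind, rows)
}

#' Input resistance from the -100 pA sweep
#'
#' \code{R_in = |steady-state - baseline| / 100 pA}, with baseline the mean
#' pre-step potential and steady state the mean over the final 100 ms of the
#' step (post-sag).
#'
#' @param sweeps A \code{\link{sweep_set}} containing a -100 pA sweep.
#' @param steady_window_s Steady-state averaging window (0.1 s).
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweeps, steady_window_s = 0.1) {
  k <- match(-100, sweeps$currents_pA)
  if (is.na(k)) stop("no -100 pA sweep present")
  v <- sweeps$traces[, k]
  t <- sweeps$time_s
  baseline <- mean(v[t < sweeps$onset_s])
  steady <- mean(v[t >= sweeps$offset_s - steady_window_s &
                     t < sweeps$offset_s])
  abs(steady - baseline) / 100 * 1000
}

#' F-I curve and per-current burst proportion
#'
#' Mean firing rate per injected current (evoked APs over the 0.5-s step)
#' and the burst proportion of each sweep's spike train (ISIs at or below
#' the burst threshold), zero by convention for sweeps without spikes.
#'
#' @param sweeps A \code{\link{sweep_set}}.
#' @param burst_threshold_ms Burst ISI threshold (10 ms).
#' @return data.frame: \code{current_pA}, \code{n_spikes}, \code{rate_hz},
#'   \code{burst_proportion}.
#' @export
fi_and_burst_curves <- function(sweeps, burst_threshold_ms = 10) {
  dur <- sweeps$offset_s - sweeps$onset_s
  rows <- lapply(seq_along(sweeps$currents_pA), function(k) {
    feats <- detect_spikes_and_features(sweeps$traces[, k], sweeps$dt)
    st <- feats$spike_time_s
    st <- st[st >= sweeps$onset_s & st < sweeps$offset_s]
    bp <- if (length(st) >= 1)
      burst_proportion(st, burst_threshold_ms)$burst_proportion else 0
    data.frame(current_pA = sweeps$currents_pA[k], n_spikes = length(st),
               rate_hz = length(st) / dur, burst_proportion = bp)
  })
  do.call(rbind, rows)
}

#' Simulate a current-clamp sweep set
#'
#' Subthreshold responses are single-exponential RC steps; action potentials
#' are stereotyped waveforms (a slow 2 mV/ms pre-ramp to threshold, a linear
#' upstroke and downstroke of slope amplitude/FWHM, a trough at threshold -
#' AHP, and a 3 mV/ms recovery) inserted at evenly spaced times, with a
#' doublet (8 ms ISI) per spike with probability \code{burstiness}. All
#' generator parameters are recoverable by the extraction functions.
#'
#' @param R_MOhm Input resistance.
#' @param tau_s Membrane time constant.
#' @param v_rest Resting potential (mV).
#' @param threshold_mV,amplitude_mV,ahp_mV,fwhm_ms AP parameters; the
#'   upstroke slope \code{amplitude_mV/fwhm_ms} must exceed 5 mV/ms.
#' @param rheobase_pA Smallest spiking current.
#' @param fi_gain Extra spikes per pA above rheobase over the step (0 turns
#'   spiking off entirely).
#' @param burstiness Doublet probability per spike.
#' @param dt Sampling interval (s), at most 0.1 ms.
#' @param currents_pA Injected current series.
#' @param pre_s,step_s,post_s Trace segmenting (step window
#'   \code{[pre_s, pre_s + step_s)}).
#' @param seed Optional seed for the doublet draws.
#' @return A \code{\link{sweep_set}}.
#' @export
simulate_sweeps <- function(R_MOhm = 150, tau_s = 0.02, v_rest = -70,
                            threshold_mV = -40, amplitude_mV = 80,
                            ahp_mV = 12, fwhm_ms = 1, rheobase_pA = 100,
                            fi_gain = 0.04, burstiness = 0, dt = 5e-5,
                            currents_pA = seq(-300, 400, by = 50),
                            pre_s = 0.1, step_s = 0.5, post_s = 0.1,
                            seed = NULL) {
  stopifnot(R_MOhm > 0, tau_s > 0, amplitude_mV > 0, fwhm_ms > 0,
            ahp_mV > 0)
  if (dt > 1e-4) stop("dt too coarse (must be <= 0.1 ms)")
  if (amplitude_mV / fwhm_ms <= 5)
    stop("upstroke slope must exceed the 5 mV/ms detection criterion")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, pre_s + step_s + post_s - dt, by = dt)
  onset <- pre_s; offset <- pre_s + step_s
  n <- length(t)
  traces <- matrix(v_rest, nrow = n, ncol = length(currents_pA))
  for (k in seq_along(currents_pA)) {
    I <- currents_pA[k]
    dv <- I * R_MOhm / 1000  # mV at steady state
    v <- rep(v_rest, n)
    instep <- t >= onset & t < offset
    v[instep] <- v_rest + dv * (1 - exp(-(t[instep] - onset) / tau_s))
    poststep <- t >= offset
    v_off <- v_rest + dv * (1 - exp(-step_s / tau_s))
    v[poststep] <- v_rest + (v_off - v_rest) * exp(-(t[poststep] - offset) /
                                                     tau_s)
    spiking <- fi_gain > 0 && I >= rheobase_pA
    if (spiking) {
      # clamp the depolarized plateau below threshold
      v <- pmin(v, threshold_mV - 3)
      nsp <- max(1, round(fi_gain * (I - rheobase_pA)))
      st <- onset + seq_len(nsp) / (nsp + 1) * step_s
      if (burstiness > 0) {
        extra <- st[stats::runif(nsp) < burstiness] + 0.008
        st <- sort(c(st, extra))
      }
      for (s0 in st) {
        # waveform segment times (ms relative to the upstroke start)
        ramp_ms <- 2; up_ms <- fwhm_ms
        down_ms <- fwhm_ms * (amplitude_mV + ahp_mV) / amplitude_mV
        rec_ms <- (ahp_mV - 3) / 3
        i0 <- round((s0 - ramp_ms / 1000) / dt) + 1
        i1 <- round((s0 + (up_ms + down_ms + max(rec_ms, 0)) / 1000) / dt) + 1
        idx <- max(1, i0):min(n, i1)
        tr <- (t[idx] - s0) * 1000  # ms relative to upstroke start
        w <- ifelse(tr < 0, threshold_mV - 4 + 2 * (tr + ramp_ms),
             ifelse(tr <= up_ms,
                    threshold_mV + amplitude_mV / fwhm_ms * tr,
             ifelse(tr <= up_ms + down_ms,
                    threshold_mV + amplitude_mV -
                      amplitude_mV / fwhm_ms * (tr - up_ms),
                    pmin(threshold_mV - ahp_mV +
                           3 * (tr - up_ms - down_ms), threshold_mV - 3))))
        v[idx] <- w
      }
    }
    traces[, k] <- v
  }
  sweep_set(t, traces, currents_pA, onset, offset)
}

#' Write a sweep set as CSV (column 1 time_s, one column per current)
#' @param sweeps A \code{sweep_set}.
#' @param path Output path.
#' @export
write_sweeps_csv <- function(sweeps, path) {
  df <- data.frame(time_s = sweeps$time_s, sweeps$traces)
  names(df) <- c("time_s", paste0("pA_", sweeps$currents_pA))
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sweep-set CSV written by \code{\link{write_sweeps_csv}}
#' @param path CSV path.
#' @param onset_s,offset_s Step window.
#' @return A \code{sweep_set}.
#' @export
read_sweeps_csv <- function(path, onset_s, offset_s) {
  df <- utils::read.csv(path, check.names = FALSE)
  currents <- as.numeric(sub("^pA_", "", names(df)[-1]))
  sweep_set(df$time_s, as.matrix(df[, -1, drop = FALSE]), currents,
            onset_s, offset_s)
}
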