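#' Sliding-window instantaneous firing rates
#'
#' The 30-min linear-chamber epoch is divided into windows of
#' \code{window_s} seconds advanced every \code{step_s} seconds, one window
#' per step (1800 windows for 30 min at the 3 s / 1 s defaults). Windows
#' reaching past the epoch end are truncated, so the last windows are
#' shorter and rates use the actual window length.
#'
#' @param spikes Sorted spike times.
#' @param epoch \code{c(start, end)} seconds; duration must be a multiple of
#'   \code{step_s}.
#' @param window_s Window length (3 s; supported range 0.5-5 s).
#' @param step_s Step (1 s).
#' @return List of class \code{instant_rate_series}: \code{values} (Hz),
#'   \code{starts}, \code{window_s}, \code{step_s}.
#' @export
instantaneous_rates <- function(spikes, epoch, window_s = 3, step_s = 1) {
  if (window_s <= 0) stop("window_s must be positive")
  dur <- epoch[2] - epoch[1]
  n <- round(dur / step_s)
  if (abs(n * step_s - dur) > 1e-9)
    stop("epoch duration must be a multiple of step_s")
  starts <- epoch[1] + (seq_len(n) - 1) * step_s
  ends <- pmin(starts + window_s, epoch[2])
  counts <- count_spikes(spikes, starts, ends)
  structure(list(values = counts / (ends - starts), starts = starts,
                 window_s = window_s, step_s = step_s),
            class = "instant_rate_series")
}

#' Summary statistics of an instantaneous-rate series
#'
#' Sigma is the sample standard deviation (1 SD) of the windowed rates; the
#' firing-rate range is maximum minus minimum. With \code{session_bounds},
#' the same statistics are computed per session from the windows whose start
#' lies inside each session.
#'
#' @param series An \code{\link{instantaneous_rates}} result.
#' @param session_bounds Optional data.frame with \code{epoch},
#'   \code{start}, \code{end} columns (see \code{\link{session_epochs}}).
#' @return List: \code{mean_rate}, \code{max_rate}, \code{min_rate},
#'   \code{fr_range}, \code{sigma}, and \code{per_session} (data.frame) when
#'   bounds are given.
#' @export
summarize_dynamics <- function(series, session_bounds = NULL) {
  v <- series$values
  if (!length(v)) stop("empty rate series")
  out <- list(mean_rate = mean(v), max_rate = max(v), min_rate = min(v),
              fr_range = max(v) - min(v), sigma = stats::sd(v))
  if (!is.null(session_bounds)) {
    rows <- lapply(seq_len(nrow(session_bounds)), function(i) {
      sel <- series$starts >= session_bounds$start[i] &
        series$starts < session_bounds$end[i]
      s <- v[sel]
      data.frame(session = session_bounds$epoch[i], mean_rate = mean(s),
                 max_rate = max(s), min_rate = min(s),
                 fr_range = max(s) - min(s), sigma = stats::sd(s))
    })
    out$per_session <- do.call(rbind, rows)
  }
  out
}

#' Histogram of rates normalized by the series maximum
#'
#' Each windowed rate is divided by the series maximum; the histogram uses
#' ten bins [0, 0.1), ..., [0.9, 1.0] (the top bin right-closed) and returns
#' proportions summing to 1.
#'
#' @param series An \code{instant_rate_series} (or numeric vector).
#' @param bin_width Bin width on the normalized axis (0.1).
#' @return Numeric vector of proportions, one per bin.
#' @export
normalized_rate_histogram <- function(series, bin_width = 0.1) {
  v <- if (inherits(series, "instant_rate_series")) series$values else series
  m <- max(v)
  if (m <= 0) stop("all-zero rate series cannot be normalized")
  x <- v / m
  nb <- round(1 / bin_width)
  idx <- pmin(floor(x / bin_width) + 1, nb)
  tabulate(idx, nbins = nb) / length(x)
}

#' Log-log regression of sigma on mean rate with a genotype comparison
#'
#' Ordinary least squares of log10(sigma) on log10(mean rate) per genotype,
#' followed by the slope-equality test and, when slopes are homogeneous, the
#' common-slope intercept (elevation) test of \code{\link{compare_slopes}}.
#' Units with nonpositive mean rate or sigma are dropped with a warning.
#'
#' @param units data.frame with columns \code{mean_rate}, \code{sigma},
#'   \code{group} (two levels).
#' @return List: per-group \code{fits} (lm objects) and \code{comparison}
#'   (see \code{\link{compare_slopes}}).
#' @export
sigma_vs_mean_regression <- function(units) {
  bad <- units$mean_rate <= 0 | units$sigma <= 0
  if (any(bad)) {
    warning(sum(bad), " unit(s) with nonpositive mean rate or sigma dropped")
    units <- units[!bad, , drop = FALSE]
  }
  groups <- unique(units$group)
  if (length(groups) != 2) stop("exactly two groups required")
  sub <- split(units, units$group)
  if (any(vapply(sub, nrow, 0L) < 3)) stop("need >= 3 units per group")
  fits <- lapply(sub, function(s) stats::lm(log10(sigma) ~ log10(mean_rate),
                                            data = s))
  cmp <- compare_slopes(log10(sub[[1]]$mean_rate), log10(sub[[1]]$sigma),
                        log10(sub[[2]]$mean_rate), log10(sub[[2]]$sigma))
  list(fits = fits, comparison = cmp, groups = groups)
}

#' Maximum delta firing rate between in-zones and center
#'
#' Zone rates are total spikes over total interval duration. The maximum
#' delta is \code{max(|FR_I1 - FR_C|, |FR_I2 - FR_C|)}; the normalized form
#' uses \code{|(FR_I - FR_C)/(FR_I + FR_C)|}.
#'
#' @param spikes Sorted spike times.
#' @param inzone_iv_1,inzone_iv_2,center_iv Valid interval sets of one
#'   session's two in-zones and center zone.
#' @return List: \code{fr_i1}, \code{fr_i2}, \code{fr_c}, \code{max_delta},
#'   \code{normalized_max_delta}.
#' @export
max_delta_fr <- function(spikes, inzone_iv_1, inzone_iv_2, center_iv) {
  zone_rate <- function(iv) {
    dur <- interval_duration(iv)
    if (!nrow(iv) || dur <= 0) stop("zone with zero total duration")
    sum(count_spikes(spikes, iv$start, iv$end)) / dur
  }
  i1 <- zone_rate(inzone_iv_1); i2 <- zone_rate(inzone_iv_2)
  cc <- zone_rate(center_iv)
  nrm <- function(a, b) if (a + b == 0) 0 else abs((a - b) / (a + b))
  list(fr_i1 = i1, fr_i2 = i2, fr_c = cc,
       max_delta = max(abs(i1 - cc), abs(i2 - cc)),
       normalized_max_delta = max(nrm(i1, cc), nrm(i2, cc)))
}
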