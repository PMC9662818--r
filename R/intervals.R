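#' Labeled time-interval sets
#'
#' Intervals are half-open \code{[start, end)} in seconds on the experiment
#' clock, sorted and non-overlapping within a set.
#'
#' @param start,end Numeric vectors of interval bounds (seconds).
#' @param label Single label for the set (e.g. \code{"sniff_left"}).
#' @param session Session identifier the set belongs to.
#' @return A data.frame of class \code{interval_set} with columns
#'   \code{start}, \code{end}, \code{label}, \code{session}.
#' @export
interval_set <- function(start = numeric(0), end = numeric(0),
                         label = NA_character_, session = NA_character_) {
  stopifnot(length(start) == length(end))
  if (length(start)) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (any(end <= start)) stop("intervals must satisfy end > start")
    if (any(start[-1] < end[-length(end)])) stop("intervals overlap")
  }
  structure(data.frame(start = as.numeric(start), end = as.numeric(end),
                       label = rep_len(label, length(start)),
                       session = rep_len(session, length(start)),
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

#' Total duration of an interval set
#' @param iv An \code{interval_set}.
#' @return Summed duration in seconds.
#' @export
interval_duration <- function(iv) sum(iv$end - iv$start)

#' Convert a per-frame membership vector to intervals
#'
#' Maximal runs of member frames become \code{[t_first, t_last + 1/fps)}
#' intervals.
#'
#' @param member Logical vector, one element per frame.
#' @param times Frame timestamps (seconds), strictly increasing.
#' @param fps Frame rate used for the trailing frame duration.
#' @param label,session Passed to \code{\link{interval_set}}.
#' @return An \code{interval_set}.
#' @export
frames_to_intervals <- function(member, times, fps,
                                label = NA_character_,
                                session = NA_character_) {
  stopifnot(length(member) == length(times))
  member[is.na(member)] <- FALSE
  if (!any(member)) return(interval_set(label = label, session = session))
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  interval_set(times[starts[keep]], times[ends[keep]] + 1 / fps,
               label = label, session = session)
}

#' Retain valid trials by duration and inter-trial gap
#'
#' Scanning in time order, intervals shorter than \code{min_duration_s} are
#' dropped first; an interval is then dropped when its start is less than
#' \code{min_gap_s} after the end of the previously retained interval.
#' Sniffing trials use (1 s, 2 s); in-zone and center trials use
#' (0.5 s, 0.5 s).
#'
#' @param iv An \code{interval_set} (sorted).
#' @param min_duration_s,min_gap_s Non-negative thresholds in seconds.
#' @return The filtered \code{interval_set}; idempotent.
#' @export
filter_valid_intervals <- function(iv, min_duration_s, min_gap_s) {
  if (min_duration_s < 0 || min_gap_s < 0)
    stop("thresholds must be non-negative")
  keep_dur <- (iv$end - iv$start) >= min_duration_s
  sub <- iv[keep_dur, , drop = FALSE]
  if (nrow(sub) <= 1) {
    out <- sub
  } else {
    keep <- logical(nrow(sub))
    keep[1] <- TRUE
    last_end <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - last_end >= min_gap_s) {
        keep[i] <- TRUE
        last_end <- sub$end[i]
      }
    }
    out <- sub[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Restrict sorted spike times to an epoch or interval set
#'
#' @param spikes Sorted numeric spike times (seconds).
#' @param iv An \code{interval_set} or a length-2 numeric \code{c(start, end)}.
#' @return Spike times falling in the half-open interval(s).
#' @export
restrict_spikes <- function(spikes, iv) {
  if (is.numeric(iv) && length(iv) == 2)
    return(spikes[spikes >= iv[1] & spikes < iv[2]])
  keep <- rep(FALSE, length(spikes))
  for (i in seq_len(nrow(iv)))
    keep <- keep | (spikes >= iv$start[i] & spikes < iv$end[i])
  spikes[keep]
}

# number of sorted spikes in each half-open [start, end)
count_spikes <- function(spikes, start, end) {
  findInterval(end, spikes, left.open = TRUE) -
    findInterval(start, spikes, left.open = TRUE)
}
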