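#' Interspike-interval histogram
#'
#' ISIs are successive spike-time differences in ms; only ISIs at or below
#' \code{max_isi_ms} enter the histogram. Proportions are normalized by the
#' total ISI count (including those beyond the cap), so they sum to the
#' fraction of ISIs within range. Group-average histograms average the
#' per-unit proportion vectors.
#'
#' @param spikes Sorted spike times (seconds); >= 2 for a non-empty result.
#' @param bin_width_ms Bin width (1 ms).
#' @param max_isi_ms Cap (200 ms).
#' @return List: \code{breaks_ms}, \code{counts}, \code{proportions},
#'   \code{n_isi_total}.
#' @export
isi_histogram <- function(spikes, bin_width_ms = 1, max_isi_ms = 200) {
  nb <- round(max_isi_ms / bin_width_ms)
  breaks <- (0:nb) * bin_width_ms
  if (length(spikes) < 2)
    return(list(breaks_ms = breaks, counts = integer(nb),
                proportions = numeric(nb), n_isi_total = 0L))
  isi <- diff(spikes) * 1000
  sel <- isi <= max_isi_ms
  # bins are (0, 1], (1, 2], ...: ceiling of the ISI in bin-width units
  # (tiny tolerance absorbs floating-point noise at bin edges)
  idx <- pmax(ceiling(isi[sel] / bin_width_ms - 1e-9), 1)
  counts <- tabulate(idx, nbins = nb)
  list(breaks_ms = breaks, counts = counts,
       proportions = counts / length(isi), n_isi_total = length(isi))
}

# logical flag per spike: participates in at least one ISI <= threshold
burst_flags <- function(spikes, threshold_ms = 10) {
  n <- length(spikes)
  if (n < 2) return(rep(FALSE, n))
  short <- diff(spikes) <= threshold_ms / 1000
  c(short, FALSE) | c(FALSE, short)
}

#' Burst proportion of a spike train
#'
#' Burst spikes are consecutive spikes joined by ISIs at or below the
#' threshold (every member of a chain counts). The proportion is
#' 100 x burst spikes / total spikes.
#'
#' @param spikes Sorted spike times (>= 1).
#' @param threshold_ms Burst ISI threshold (default 10 ms, sweepable 5-30).
#' @return List: \code{threshold_ms}, \code{n_burst_spikes},
#'   \code{n_total_spikes}, \code{burst_proportion} (percent).
#' @export
burst_proportion <- function(spikes, threshold_ms = 10) {
  if (!length(spikes)) stop("empty spike train")
  fl <- burst_flags(spikes, threshold_ms)
  list(threshold_ms = threshold_ms, n_burst_spikes = sum(fl),
       n_total_spikes = length(spikes),
       burst_proportion = 100 * mean(fl))
}

#' Remove burst or tonic spikes
#'
#' \code{mode = "burst"} eliminates every spike participating in an ISI at or
#' below the threshold; \code{mode = "tonic"} eliminates the complement. The
#' two outputs partition the input exactly.
#'
#' @param spikes Sorted spike times.
#' @param mode \code{"burst"} or \code{"tonic"} (what is eliminated).
#' @param threshold_ms Burst ISI threshold (10 ms).
#' @return The retained spike times.
#' @export
eliminate_spikes <- function(spikes, mode = c("burst", "tonic"),
                             threshold_ms = 10) {
  mode <- match.arg(mode)
  fl <- burst_flags(spikes, threshold_ms)
  if (mode == "burst") spikes[!fl] else spikes[fl]
}

#' Burst proportion in rest vs linear-chamber epochs
#'
#' Spikes are restricted to each epoch before ISIs are computed (no ISI
#' spans the epoch boundary); the burst proportion is evaluated for each
#' threshold of the sweep.
#'
#' @param spikes Sorted spike times.
#' @param rest_epoch,chamber_epoch \code{c(start, end)} seconds.
#' @param thresholds_ms ISI thresholds to sweep (5-30 ms).
#' @return data.frame: \code{epoch}, \code{threshold_ms}, \code{n_burst},
#'   \code{n_total}, \code{proportion} (NA when an epoch holds no spikes).
#' @export
burst_rest_vs_chamber <- function(spikes, rest_epoch, chamber_epoch,
                                  thresholds_ms = 5:30) {
  one <- function(sp, name) {
    do.call(rbind, lapply(thresholds_ms, function(th) {
      if (!length(sp))
        return(data.frame(epoch = name, threshold_ms = th, n_burst = NA,
                          n_total = 0L, proportion = NA_real_))
      bp <- burst_proportion(sp, th)
      data.frame(epoch = name, threshold_ms = th,
                 n_burst = bp$n_burst_spikes, n_total = bp$n_total_spikes,
                 proportion = bp$burst_proportion)
    }))
  }
  rbind(one(restrict_spikes(spikes, rest_epoch), "rest"),
        one(restrict_spikes(spikes, chamber_epoch), "chamber"))
}
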