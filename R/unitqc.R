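#' Putative excitatory/inhibitory classification
#'
#' Units are classified from two waveform features: pExc requires half-valley
#' width strictly above the threshold AND peak-to-valley ratio strictly above
#' its threshold; pInh requires both strictly below. Discordant or
#' exact-boundary features give \code{"unclassified"} (excluded downstream).
#' Thresholds are applied to the stored feature values as recorded, with no
#' unit conversion.
#'
#' @param hvw Half-valley width.
#' @param pvr Peak-to-valley ratio.
#' @param hvw_threshold,pvr_threshold Classification thresholds (200, 1.4).
#' @return \code{"pExc"}, \code{"pInh"} or \code{"unclassified"} (vectorized).
#' @export
classify_unit <- function(hvw, pvr, hvw_threshold = 200,
                          pvr_threshold = 1.4) {
  stopifnot(all(hvw > 0), all(pvr > 0))
  out <- rep("unclassified", length(hvw))
  out[hvw > hvw_threshold & pvr > pvr_threshold] <- "pExc"
  out[hvw < hvw_threshold & pvr < pvr_threshold] <- "pInh"
  out
}

#' Cluster-quality filter
#'
#' @param isolation_distance,l_ratio Cluster metrics.
#' @param isolation_min,l_ratio_max Cutoffs (strict: > 25 and < 0.1).
#' @return Logical (vectorized).
#' @export
quality_filter <- function(isolation_distance, l_ratio, isolation_min = 25,
                           l_ratio_max = 0.1) {
  if (any(is.na(isolation_distance)) || any(is.na(l_ratio)))
    stop("missing cluster-quality metadata")
  isolation_distance > isolation_min & l_ratio < l_ratio_max
}

#' Firing-rate inclusion filter
#'
#' Mean rate over the linear-chamber epoch must be at least 0.5 Hz
#' (inclusive). Rest-period rate comparisons bypass this filter.
#'
#' @param spikes Spike times restricted to the linear-chamber epoch.
#' @param duration_s Epoch duration (1800 s for the 30-min assay).
#' @param min_rate_hz Threshold (0.5 Hz).
#' @return Logical.
#' @export
rate_filter <- function(spikes, duration_s = 1800, min_rate_hz = 0.5) {
  if (duration_s <= 0) stop("nonpositive duration")
  length(spikes) / duration_s >= min_rate_hz
}

#' Exclude units whose experiment misses valid trials
#'
#' A unit is retained only if each of the six targets (left/right empty in
#' E-E; social/object in each S-O session) has at least one valid sniffing
#' trial and one valid in-zone trial.
#'
#' @param units List of unit records.
#' @param valid_sniff,valid_inzone Named lists of valid
#'   \code{\link{interval_set}}s keyed \code{session.target} as produced by
#'   \code{\link{detect_events}}.
#' @return Logical vector (one entry per unit): retained or not.
#' @export
exclude_units_missing_trials <- function(units, valid_sniff, valid_inzone) {
  required <- c("EE.left_empty", "EE.right_empty", "SO1.social", "SO1.object",
                "SO2.social", "SO2.object")
  ok <- all(vapply(required, function(k) {
    !is.null(valid_sniff[[k]]) && nrow(valid_sniff[[k]]) >= 1 &&
      !is.null(valid_inzone[[k]]) && nrow(valid_inzone[[k]]) >= 1
  }, logical(1)))
  rep(ok, length(units))
}

#' Unit QC report
#'
#' Applies waveform classification, cluster-quality, firing-rate and
#' valid-trial filters to every unit of a bundle.
#'
#' @param bundle An \code{\link{experiment_bundle}}.
#' @param events Result of \code{\link{detect_events}} for the bundle.
#' @return data.frame: \code{unit_id}, \code{cell_class},
#'   \code{pass_quality}, \code{pass_rate}, \code{pass_trials},
#'   \code{included} (pExc passing all filters).
#' @export
unit_qc_report <- function(bundle, events) {
  ep <- session_epochs(bundle$layout)
  lc <- c(min(ep$start[ep$epoch != "rest"]), max(ep$end))
  dur <- lc[2] - lc[1]
  ids <- vapply(bundle$units, `[[`, "", "unit_id")
  cls <- classify_unit(vapply(bundle$units, `[[`, 0, "hvw"),
                       vapply(bundle$units, `[[`, 0, "pvr"))
  qual <- quality_filter(vapply(bundle$units, `[[`, 0, "isolation_distance"),
                         vapply(bundle$units, `[[`, 0, "l_ratio"))
  rate <- vapply(bundle$units, function(u)
    rate_filter(restrict_spikes(u$spikes, lc), dur), logical(1))
  trials <- exclude_units_missing_trials(bundle$units, events$sniff,
                                         events$inzone)
  data.frame(unit_id = ids, cell_class = cls, pass_quality = qual,
             pass_rate = rate, pass_trials = trials,
             included = cls == "pExc" & qual & rate & trials,
             stringsAsFactors = FALSE)
}
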