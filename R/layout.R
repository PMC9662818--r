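#' Session layout of a linear-chamber experiment
#'
#' The paradigm is a 5-min rest period followed by three 10-min sessions in a
#' 45 x 10 cm corridor: both side chambers empty (E-E), then social and object
#' targets (first S-O), then the same targets with sides exchanged (second
#' S-O).
#'
#' @param rest_duration Rest-period duration in seconds.
#' @param session_durations Named vector of the three chamber-session
#'   durations in seconds, order \code{EE}, \code{SO1}, \code{SO2}.
#' @param fps Tracking frame rate (frames/second).
#' @param chamber_length,chamber_width Corridor dimensions in cm. The corridor
#'   is divided downstream into five equal 9-cm sections.
#' @return An object of class \code{session_layout}.
#' @export
session_layout <- function(rest_duration = 300,
                           session_durations = c(EE = 600, SO1 = 600, SO2 = 600),
                           fps = 30, chamber_length = 45, chamber_width = 10) {
  stopifnot(rest_duration > 0, all(session_durations > 0), fps > 0,
            chamber_length > 0, chamber_width > 0,
            length(session_durations) == 3)
  if (is.null(names(session_durations)))
    names(session_durations) <- c("EE", "SO1", "SO2")
  structure(list(rest_duration = rest_duration,
                 session_durations = session_durations,
                 fps = fps, chamber_length = chamber_length,
                 chamber_width = chamber_width),
            class = "session_layout")
}

#' Epoch boundaries of a layout
#'
#' @param layout A \code{session_layout}.
#' @return A data.frame with columns \code{epoch}, \code{start}, \code{end}
#'   (seconds, half-open), rows \code{rest}, \code{EE}, \code{SO1},
#'   \code{SO2}.
#' @export
session_epochs <- function(layout) {
  ends <- cumsum(c(layout$rest_duration, layout$session_durations))
  starts <- c(0, ends[-length(ends)])
  data.frame(epoch = c("rest", names(layout$session_durations)),
             start = unname(starts), end = unname(ends),
             stringsAsFactors = FALSE)
}

#' Zone geometry of the corridor
#'
#' Sniffing requires the nose within 3 cm of a chamber face; in-zone requires
#' the body center (nose/tail-base midpoint) within 9 cm; the center zone is
#' the middle of the five equal 9-cm sections. Proximal interaction is a
#' nose-to-target distance below 2.5 cm, distal between 2.5 and 10 cm.
#'
#' @param sniff_depth,inzone_depth,section_length,proximal_max,distal_max cm.
#' @return An object of class \code{zone_geometry}.
#' @export
zone_geometry <- function(sniff_depth = 3, inzone_depth = 9,
                          section_length = 9, proximal_max = 2.5,
                          distal_max = 10) {
  stopifnot(sniff_depth > 0, sniff_depth < inzone_depth,
            inzone_depth <= section_length, proximal_max < distal_max)
  structure(list(sniff_depth = sniff_depth, inzone_depth = inzone_depth,
                 section_length = section_length, proximal_max = proximal_max,
                 distal_max = distal_max),
            class = "zone_geometry")
}

#' Printed default analysis parameters
#'
#' One place holding every analysis default so configurations and audits can
#' refer to them by name.
#'
#' @return Named list of defaults.
#' @export
lc_defaults <- function() {
  list(sniff_depth_cm = 3, inzone_depth_cm = 9, section_length_cm = 9,
       proximal_max_cm = 2.5, distal_max_cm = 10,
       sniff_min_duration_s = 1, sniff_min_gap_s = 2,
       inzone_min_duration_s = 0.5, inzone_min_gap_s = 0.5,
       proximity_min_duration_s = 1,
       rate_bin_s = 0.5, roc_bins = 100, n_shuffles = 1000,
       null_quantiles = c(0.005, 0.995), min_bins = 40,
       sdf_bin_s = 0.25, sdf_window_s = c(-1.5, 3),
       svm_min_trials = 10, svm_reps = 100, correct_neuron_pct = 55,
       rate_window_s = 3, rate_step_s = 1, n_windows_30min = 1800,
       isi_max_ms = 200, burst_threshold_ms = 10,
       burst_threshold_range_ms = c(5, 30),
       min_rate_hz = 0.5, hvw_threshold = 200, pvr_threshold = 1.4,
       isolation_distance_min = 25, l_ratio_max = 0.1,
       step_duration_s = 0.5, currents_pA = seq(-300, 400, by = 50),
       dvdt_threshold_mV_per_ms = 5)
}
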