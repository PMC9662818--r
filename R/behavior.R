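#' Zone-occupancy intervals from tracking
#'
#' Sniffing: nose within \code{sniff_depth} (3 cm) of a chamber face,
#' measured as perpendicular distance to the face plane. In-zone: body center
#' (nose/tail-base midpoint) within \code{inzone_depth} (9 cm) of a face.
#' Center: body center within the middle of the five equal 9-cm sections of
#' the 45-cm corridor, i.e. x in [18, 27).
#'
#' @param track A \code{\link{tracking_series}}.
#' @param geom A \code{\link{zone_geometry}}.
#' @param kind One of \code{"sniff"}, \code{"inzone"}, \code{"center"}.
#' @param side \code{"left"} (face at x = 0) or \code{"right"} (face at
#'   x = chamber length); ignored for \code{"center"}.
#' @param min_likelihood Frames with a required-part likelihood below this are
#'   filled by last-observation-carried-forward.
#' @return An \code{\link{interval_set}} of maximal membership runs, each
#'   frame contributing \code{1/fps} seconds.
#' @export
compute_zone_intervals <- function(track, geom = zone_geometry(),
                                   kind = c("sniff", "inzone", "center"),
                                   side = c("left", "right", "none"),
                                   min_likelihood = 0.9) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  L <- track$chamber_length
  if (kind == "sniff") {
    nose <- part_xy(track, "nose", min_likelihood)
    member <- if (side == "left") nose$x <= geom$sniff_depth
              else nose$x >= L - geom$sniff_depth
    label <- paste0("sniff_", side)
  } else if (kind == "inzone") {
    bc <- body_center_xy(track, min_likelihood)
    member <- if (side == "left") bc$x <= geom$inzone_depth
              else bc$x >= L - geom$inzone_depth
    label <- paste0("inzone_", side)
  } else {
    bc <- body_center_xy(track, min_likelihood)
    lo <- 2 * geom$section_length
    hi <- 3 * geom$section_length
    member <- bc$x >= lo & bc$x < hi
    label <- "center"
  }
  frames_to_intervals(member, track$times, track$fps, label = label,
                      session = track$session)
}

#' Proximal/distal interaction intervals and distance profile
#'
#' For a social target the per-frame distance is nose-to-nose; for an object
#' target it is the distance from the subject's nose to the center of the
#' object chamber face. Proximal frames have distance in [0, 2.5) cm, distal
#' in [2.5, 10) cm. Valid proximal/distal trials last at least 1 s.
#'
#' @param subject Subject \code{tracking_series} (nose required).
#' @param target_kind \code{"social"} or \code{"object"}.
#' @param target For social, a \code{tracking_series} containing
#'   \code{target_nose}; for object, the face side \code{"left"}/\code{"right"}
#'   or an \code{c(x, y)} point.
#' @param geom A \code{\link{zone_geometry}}.
#' @param min_duration_s Valid-trial duration threshold (1 s).
#' @param bin_cm Distance-profile bin width (0.5 cm).
#' @param min_likelihood Likelihood gate, as elsewhere.
#' @return List with \code{proximal} and \code{distal}
#'   \code{\link{interval_set}}s (valid trials), and \code{distance_profile},
#'   a data.frame of occupancy seconds per distance bin.
#' @export
compute_proximity_intervals <- function(subject,
                                        target_kind = c("social", "object"),
                                        target, geom = zone_geometry(),
                                        min_duration_s = 1, bin_cm = 0.5,
                                        min_likelihood = 0.9) {
  target_kind <- match.arg(target_kind)
  nose <- part_xy(subject, "nose", min_likelihood)
  if (target_kind == "social") {
    if (is.character(target) || (is.numeric(target) && length(target) == 2))
      stop("social proximity requires target nose tracking")
    tn <- part_xy(target, "target_nose", min_likelihood)
    d <- sqrt((nose$x - tn$x)^2 + (nose$y - tn$y)^2)
  } else {
    pt <- if (is.numeric(target) && length(target) == 2) target
          else if (identical(target, "left")) c(0, subject$chamber_width / 2)
          else if (identical(target, "right"))
            c(subject$chamber_length, subject$chamber_width / 2)
          else stop("object target must be a side or an (x, y) point")
    d <- sqrt((nose$x - pt[1])^2 + (nose$y - pt[2])^2)
  }
  prox <- frames_to_intervals(d >= 0 & d < geom$proximal_max, subject$times,
                              subject$fps, label = "proximal",
                              session = subject$session)
  dist <- frames_to_intervals(d >= geom$proximal_max & d < geom$distal_max,
                              subject$times, subject$fps, label = "distal",
                              session = subject$session)
  prox <- filter_valid_intervals(prox, min_duration_s, 0)
  dist <- filter_valid_intervals(dist, min_duration_s, 0)
  edges <- seq(0, ceiling(max(d) / bin_cm) * bin_cm, by = bin_cm)
  idx <- pmin(findInterval(d, edges, rightmost.closed = FALSE),
              length(edges) - 1)
  dur <- tabulate(idx, nbins = length(edges) - 1) / subject$fps
  profile <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        duration_s = dur)
  list(proximal = prox, distal = dist, distance_profile = profile)
}

#' Total distance moved (cm)
#'
#' Sum of frame-to-frame Euclidean displacements of the body center
#' (nose/tail-base midpoint).
#'
#' @param track A \code{tracking_series}.
#' @param min_likelihood Likelihood gate.
#' @return Distance in cm (0 with fewer than 2 frames).
#' @export
distance_moved <- function(track, min_likelihood = 0.9) {
  bc <- body_center_xy(track, min_likelihood)
  if (nrow(bc) < 2) return(0)
  sum(sqrt(diff(bc$x)^2 + diff(bc$y)^2))
}

#' All behavioral event sets for one experiment
#'
#' Computes, per session, the sniff/in-zone intervals on both sides plus the
#' center-zone intervals, applies the valid-trial rules (sniffing: >= 1 s
#' duration, >= 2 s gap; in-zone/center: >= 0.5 s / >= 0.5 s), and maps sides
#' to targets using the experiment's target placement.
#'
#' @param tracking Named list of \code{tracking_series}, one per session.
#' @param targets data.frame with columns \code{session}, \code{side},
#'   \code{target} mapping each face to its target.
#' @param geom A \code{\link{zone_geometry}}.
#' @param min_likelihood Likelihood gate.
#' @return List with elements \code{sniff} (named by
#'   \code{session.target}), \code{inzone} (idem), \code{center} (named by
#'   session), all valid-trial filtered, and \code{raw_sniff} (unfiltered).
#' @export
detect_events <- function(tracking, targets, geom = zone_geometry(),
                          min_likelihood = 0.9) {
  d <- lc_defaults()
  sniff <- list(); inzone <- list(); center <- list(); raw_sniff <- list()
  for (i in seq_len(nrow(targets))) {
    ses <- targets$session[i]; side <- targets$side[i]
    tgt <- targets$target[i]
    track <- tracking[[ses]]
    if (is.null(track)) stop("missing tracking for session ", ses)
    key <- paste(ses, tgt, sep = ".")
    sv <- compute_zone_intervals(track, geom, "sniff", side, min_likelihood)
    raw_sniff[[key]] <- sv
    sniff[[key]] <- filter_valid_intervals(sv, d$sniff_min_duration_s,
                                           d$sniff_min_gap_s)
    iz <- compute_zone_intervals(track, geom, "inzone", side, min_likelihood)
    inzone[[key]] <- filter_valid_intervals(iz, d$inzone_min_duration_s,
                                            d$inzone_min_gap_s)
  }
  for (ses in unique(targets$session)) {
    cz <- compute_zone_intervals(tracking[[ses]], geom, "center", "none",
                                 min_likelihood)
    center[[ses]] <- filter_valid_intervals(cz, d$inzone_min_duration_s,
                                            d$inzone_min_gap_s)
  }
  list(sniff = sniff, inzone = inzone, center = center,
       raw_sniff = raw_sniff)
}

#' Pool event sets by analysis target
#'
#' Empty pools the left and right sniff trials of the E-E session; social and
#' object pool their sniff trials over both S-O sessions; center pools the
#' center-zone trials of all three sessions.
#'
#' @param events Result of \code{\link{detect_events}}.
#' @return List with \code{sniff} (named \code{empty}, \code{social},
#'   \code{object}) and \code{center} interval sets.
#' @export
pool_target_events <- function(events) {
  pool <- function(keys) {
    ivs <- events$sniff[keys]
    ivs <- ivs[!vapply(ivs, is.null, logical(1))]
    df <- do.call(rbind, lapply(ivs, as.data.frame))
    if (is.null(df) || !nrow(df))
      return(interval_set())
    interval_set(df$start, df$end, label = "sniff")
  }
  keys <- names(events$sniff)
  emp <- keys[grepl("^EE\\.", keys)]
  soc <- keys[grepl("\\.social$", keys)]
  obj <- keys[grepl("\\.object$", keys)]
  cen <- do.call(rbind, lapply(events$center, as.data.frame))
  center <- if (is.null(cen) || !nrow(cen)) interval_set()
            else interval_set(cen$start, cen$end, label = "center")
  list(sniff = list(empty = pool(emp), social = pool(soc), object = pool(obj)),
       center = center)
}
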