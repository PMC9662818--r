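#' Per-session tracking series
#'
#' Holds per-frame coordinates (cm, chamber frame) for named body parts of the
#' subject mouse (nose, left_ear, right_ear, body_center, tail_base) and, when
#' a social target is present, of the target (target_nose,
#' target_body_center). Timestamps are on the experiment clock.
#'
#' @param times Frame timestamps in seconds, strictly increasing.
#' @param parts Named list; each element a data.frame with columns \code{x},
#'   \code{y}, \code{likelihood}.
#' @param fps Frame rate.
#' @param session Session identifier.
#' @param chamber_length,chamber_width Corridor dimensions (cm).
#' @return Object of class \code{tracking_series}.
#' @export
tracking_series <- function(times, parts, fps, session = NA_character_,
                            chamber_length = 45, chamber_width = 10) {
  stopifnot(is.list(parts), length(parts) > 0, !is.null(names(parts)))
  n <- length(times)
  for (p in names(parts)) {
    if (!all(c("x", "y") %in% names(parts[[p]])))
      stop("part '", p, "' lacks x/y columns")
    if (nrow(parts[[p]]) != n)
      stop("part '", p, "' length differs from timestamps")
    if (is.null(parts[[p]]$likelihood)) parts[[p]]$likelihood <- 1
  }
  structure(list(times = as.numeric(times), parts = parts, fps = fps,
                 session = session, chamber_length = chamber_length,
                 chamber_width = chamber_width),
            class = "tracking_series")
}

#' @export
print.tracking_series <- function(x, ...) {
  cat("<tracking_series>", x$session, ":", length(x$times), "frames @",
      x$fps, "fps; parts:", paste(names(x$parts), collapse = ", "), "\n")
  invisible(x)
}

# Fill frames whose likelihood is below `min_likelihood` by carrying the last
# well-tracked coordinate forward (the first frames fall back to the first
# good one).
fill_low_likelihood <- function(part, min_likelihood = 0.9) {
  bad <- part$likelihood < min_likelihood
  if (!any(bad)) return(part)
  good_idx <- which(!bad)
  if (!length(good_idx)) stop("no frames above the likelihood threshold")
  carry <- cumsum(!bad)
  carry[carry == 0] <- 1
  src <- good_idx[carry]
  part$x <- part$x[src]
  part$y <- part$y[src]
  part
}

# coordinates of a required part after likelihood gating
part_xy <- function(track, part, min_likelihood = 0.9) {
  if (is.null(track$parts[[part]]))
    stop("required body part '", part, "' is not tracked")
  fill_low_likelihood(track$parts[[part]], min_likelihood)
}

# body center = geometric midpoint of nose and tail_base
body_center_xy <- function(track, min_likelihood = 0.9) {
  nose <- part_xy(track, "nose", min_likelihood)
  tail <- part_xy(track, "tail_base", min_likelihood)
  data.frame(x = (nose$x + tail$x) / 2, y = (nose$y + tail$y) / 2)
}

#' Write a tracking series as a DeepLabCut-style CSV
#'
#' Three header rows (scorer / bodyparts / coords) followed by a frame index
#' and an (x, y, likelihood) triplet per body part. Coordinates in cm.
#'
#' @param track A \code{tracking_series}.
#' @param path Output file path.
#' @export
write_tracking_csv <- function(track, path) {
  parts <- names(track$parts)
  scorer <- c("scorer", rep("linchamber", 3 * length(parts)))
  bodyparts <- c("bodyparts", rep(parts, each = 3))
  coords <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  n <- length(track$times)
  mat <- do.call(cbind, lapply(track$parts, function(p)
    cbind(p$x, p$y, p$likelihood)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(scorer, collapse = ","), con)
  writeLines(paste(bodyparts, collapse = ","), con)
  writeLines(paste(coords, collapse = ","), con)
  body <- cbind(seq_len(n) - 1L, format(mat, digits = 15, trim = TRUE,
                                        scientific = FALSE))
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a DeepLabCut-style tracking CSV
#'
#' @param path CSV path written by \code{\link{write_tracking_csv}} or
#'   exported by DeepLabCut (single-scorer layout).
#' @param fps Frame rate used to reconstruct timestamps.
#' @param t0 Time of the first frame on the experiment clock (seconds).
#' @param session,chamber_length,chamber_width Metadata for the result.
#' @return A \code{tracking_series}.
#' @export
read_tracking_csv <- function(path, fps, t0 = 0, session = NA_character_,
                              chamber_length = 45, chamber_width = 10) {
  hdr <- readLines(path, n = 3)
  bodyparts <- strsplit(hdr[2], ",", fixed = TRUE)[[1]][-1]
  coords <- strsplit(hdr[3], ",", fixed = TRUE)[[1]][-1]
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  frames <- dat[[1]]
  vals <- as.matrix(dat[, -1, drop = FALSE])
  parts <- list()
  for (p in unique(bodyparts)) {
    cols <- which(bodyparts == p)
    names(cols) <- coords[cols]
    parts[[p]] <- data.frame(x = vals[, cols[["x"]]],
                             y = vals[, cols[["y"]]],
                             likelihood = vals[, cols[["likelihood"]]])
  }
  tracking_series(t0 + frames / fps, parts, fps, session = session,
                  chamber_length = chamber_length,
                  chamber_width = chamber_width)
}
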