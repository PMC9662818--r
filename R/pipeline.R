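#' Slope and elevation comparison of two simple linear regressions
#'
#' Ordinary least squares is fitted per group. Slope equality is tested by
#' \code{t = (b1 - b2)/SE} with the pooled residual variance,
#' \code{df = n1 + n2 - 4}. When the slopes are homogeneous (p above
#' \code{alpha}), a common-slope model is fitted and the intercepts
#' (elevations) are compared with \code{df = n1 + n2 - 3}.
#'
#' @param x1,y1,x2,y2 Data of the two groups (>= 3 points each).
#' @param alpha Homogeneity level for proceeding to the elevation test.
#' @return List: \code{slope1}, \code{slope2}, \code{slope_diff},
#'   \code{t_slope}, \code{df_slope}, \code{p_slope}; and when slopes are
#'   homogeneous \code{common_slope}, \code{intercept1}, \code{intercept2},
#'   \code{t_intercept}, \code{df_intercept}, \code{p_intercept}.
#' @export
compare_slopes <- function(x1, y1, x2, y2, alpha = 0.05) {
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(n1 >= 3, n2 >= 3, length(y1) == n1, length(y2) == n2)
  sxx1 <- sum((x1 - mean(x1))^2); sxx2 <- sum((x2 - mean(x2))^2)
  if (sxx1 == 0 || sxx2 == 0) stop("degenerate x (zero variance)")
  sxy1 <- sum((x1 - mean(x1)) * (y1 - mean(y1)))
  sxy2 <- sum((x2 - mean(x2)) * (y2 - mean(y2)))
  b1 <- sxy1 / sxx1; b2 <- sxy2 / sxx2
  ss1 <- sum((y1 - mean(y1) - b1 * (x1 - mean(x1)))^2)
  ss2 <- sum((y2 - mean(y2) - b2 * (x2 - mean(x2)))^2)
  df_s <- n1 + n2 - 4
  s2 <- (ss1 + ss2) / df_s
  se <- sqrt(s2 * (1 / sxx1 + 1 / sxx2))
  t_s <- (b1 - b2) / se
  p_s <- 2 * stats::pt(-abs(t_s), df_s)
  out <- list(slope1 = b1, slope2 = b2, slope_diff = b1 - b2, t_slope = t_s,
              df_slope = df_s, p_slope = p_s)
  if (p_s >= alpha) {
    bc <- (sxy1 + sxy2) / (sxx1 + sxx2)
    ssc <- sum((y1 - mean(y1) - bc * (x1 - mean(x1)))^2) +
      sum((y2 - mean(y2) - bc * (x2 - mean(x2)))^2)
    df_i <- n1 + n2 - 3
    s2c <- ssc / df_i
    num <- mean(y1) - mean(y2) - bc * (mean(x1) - mean(x2))
    sei <- sqrt(s2c * (1 / n1 + 1 / n2 +
                         (mean(x1) - mean(x2))^2 / (sxx1 + sxx2)))
    t_i <- num / sei
    out$common_slope <- bc
    out$intercept1 <- mean(y1) - bc * mean(x1)
    out$intercept2 <- mean(y2) - bc * mean(x2)
    out$t_intercept <- t_i
    out$df_intercept <- df_i
    out$p_intercept <- 2 * stats::pt(-abs(t_i), df_i)
  }
  out
}

#' Group summary of unit classifications
#'
#' Per-genotype unit counts and percentages (pExc/pInh out of total recorded
#' units), and when encoding results are supplied, target-neuron counts and
#' the Venn region counts of empty/social/object membership plus 2x2 tables
#' for exact tests.
#'
#' @param qc data.frame with \code{unit_id}, \code{genotype},
#'   \code{cell_class} columns.
#' @param encoding Optional data.frame from \code{\link{classify_all_units}}
#'   joined with genotypes (columns \code{unit_id}, \code{genotype},
#'   \code{target}, \code{label}).
#' @return List with \code{cell_counts} (data.frame) and, when encoding is
#'   given, \code{target_counts} and \code{venn} per genotype.
#' @export
proportion_summary <- function(qc, encoding = NULL) {
  counts <- do.call(rbind, lapply(split(qc, qc$genotype), function(g)
    data.frame(genotype = g$genotype[1], n_total = nrow(g),
               n_pexc = sum(g$cell_class == "pExc"),
               n_pinh = sum(g$cell_class == "pInh"),
               pct_pexc = 100 * sum(g$cell_class == "pExc") / nrow(g),
               pct_pinh = 100 * sum(g$cell_class == "pInh") / nrow(g))))
  rownames(counts) <- NULL
  out <- list(cell_counts = counts)
  if (!is.null(encoding) && nrow(encoding)) {
    resp <- encoding[encoding$label == "responsive", , drop = FALSE]
    tc <- do.call(rbind, lapply(split(encoding, encoding$genotype),
                                function(g) {
      tot <- length(unique(g$unit_id))
      r <- g[g$label == "responsive", , drop = FALSE]
      do.call(rbind, lapply(c("empty", "social", "object"), function(tg)
        data.frame(genotype = g$genotype[1], target = tg,
                   n_responsive = length(unique(r$unit_id[r$target == tg])),
                   n_total = tot,
                   pct = 100 * length(unique(r$unit_id[r$target == tg])) /
                     max(tot, 1))))
    }))
    rownames(tc) <- NULL
    venn <- lapply(split(encoding, encoding$genotype), function(g) {
      ids <- unique(g$unit_id)
      memb <- sapply(c("empty", "social", "object"), function(tg)
        ids %in% g$unit_id[g$label == "responsive" & g$target == tg])
      memb <- matrix(memb, ncol = 3,
                     dimnames = list(NULL, c("E", "S", "O")))
      key <- apply(memb, 1, function(m)
        paste0(ifelse(m, c("E", "S", "O"), ""), collapse = ""))
      key[key == ""] <- "none"
      table(key)
    })
    out$target_counts <- tc
    out$venn <- venn
  }
  out
}

#' Run the full analysis pipeline on an experiment bundle
#'
#' Executes behavior event detection, unit QC, encoding, decoding, dynamics
#' and burst analyses, writes the summary TSVs to \code{out_dir}, and emits
#' a manifest with a content hash per file. Deterministic given the bundle
#' and \code{seed}.
#'
#' @param bundle An \code{\link{experiment_bundle}} (or a directory written
#'   by \code{\link{write_experiment}}).
#' @param out_dir Output directory.
#' @param seed Seed for the stochastic stages (decoding, shuffles).
#' @param n_shuffles,svm_reps,ensemble_sizes Analysis scale knobs; defaults
#'   are the printed values (1000 shuffles, 100 repetitions).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_all <- function(bundle, out_dir, seed = 1, n_shuffles = 1000,
                    svm_reps = 100, ensemble_sizes = c(1, 5, 10)) {
  if (is.character(bundle)) bundle <- read_experiment(bundle)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("stage setup: cannot create ", out_dir)
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    name
  }
  files <- character(0)

  events <- detect_events(bundle$tracking, bundle$targets)
  ev_df <- do.call(rbind, c(lapply(names(events$sniff), function(k)
    cbind(set = k, as.data.frame(events$sniff[[k]]))),
    lapply(names(events$center), function(k)
      cbind(set = paste0(k, ".center"), as.data.frame(events$center[[k]])))))
  files <- c(files, wr(ev_df, "events.tsv"))

  qc <- unit_qc_report(bundle, events)
  qc$genotype <- vapply(bundle$units, `[[`, "", "genotype")
  files <- c(files, wr(qc, "unit_qc.tsv"))
  included <- qc$unit_id[qc$included]

  enc <- classify_all_units(bundle, events, unit_ids = included,
                            n_shuffles = n_shuffles)
  if (!is.null(enc)) {
    enc$genotype <- qc$genotype[match(enc$unit_id, qc$unit_id)]
    files <- c(files, wr(enc, "encoding.tsv"))
  }

  set.seed(seed)
  dec_rows <- list()
  for (ses in c("EE", "SO1")) {
    tabs <- session_trial_tables(bundle, events, ses, unit_ids = included)
    if (length(tabs) < 1) next
    for (es in ensemble_sizes[ensemble_sizes <= length(tabs)]) {
      for (sh in c(FALSE, TRUE)) {
        r <- population_decoding(tabs, es, n_rep = svm_reps, shuffled = sh)
        dec_rows[[length(dec_rows) + 1]] <-
          data.frame(session = ses, ensemble_size = es, shuffled = sh,
                     mean_accuracy = r$mean_accuracy,
                     sd_accuracy = stats::sd(r$accuracies))
      }
    }
  }
  if (length(dec_rows))
    files <- c(files, wr(do.call(rbind, dec_rows), "decoding.tsv"))

  ep <- session_epochs(bundle$layout)
  lc <- c(min(ep$start[ep$epoch != "rest"]), max(ep$end))
  ids <- vapply(bundle$units, `[[`, "", "unit_id")
  dyn <- do.call(rbind, lapply(included, function(id) {
    u <- bundle$units[[match(id, ids)]]
    s <- summarize_dynamics(instantaneous_rates(u$spikes, lc))
    data.frame(unit_id = id, mean_rate = s$mean_rate, max_rate = s$max_rate,
               min_rate = s$min_rate, fr_range = s$fr_range,
               sigma = s$sigma)
  }))
  if (!is.null(dyn)) files <- c(files, wr(dyn, "dynamics.tsv"))

  rest <- c(0, bundle$layout$rest_duration)
  bur <- do.call(rbind, lapply(included, function(id) {
    u <- bundle$units[[match(id, ids)]]
    cbind(unit_id = id, burst_rest_vs_chamber(u$spikes, rest, lc,
                                              thresholds_ms = c(5, 10, 20, 30)))
  }))
  if (!is.null(bur)) files <- c(files, wr(bur, "bursts.tsv"))

  summ <- proportion_summary(qc, enc)
  files <- c(files, wr(summ$cell_counts, "cell_counts.tsv"))

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))))
  files <- c(files, wr(manifest, "manifest.tsv"))
  invisible(list(events = events, qc = qc, encoding = enc,
                 decoding = if (length(dec_rows)) do.call(rbind, dec_rows),
                 dynamics = dyn, bursts = bur, summary = summ,
                 manifest = manifest))
}
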