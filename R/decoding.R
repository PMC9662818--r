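#' Trial firing-rate table for one unit
#'
#' One firing rate per valid sniffing trial (spikes in trial / trial
#' duration) for each of the two classes to be decoded (left vs right in the
#' E-E session, social vs object in an S-O session).
#'
#' @param spikes Sorted spike times.
#' @param class_a_iv,class_b_iv Valid sniffing trials of the two classes.
#' @param unit_id Identifier carried along.
#' @return List of class \code{trial_rate_table}: \code{unit_id}, \code{a},
#'   \code{b} (numeric rate vectors).
#' @export
trial_rate_table <- function(spikes, class_a_iv, class_b_iv,
                             unit_id = NA_character_) {
  rate <- function(iv) count_spikes(spikes, iv$start, iv$end) /
    (iv$end - iv$start)
  structure(list(unit_id = unit_id, a = rate(class_a_iv),
                 b = rate(class_b_iv)),
            class = "trial_rate_table")
}

# leave-one-out CV on a 10+10 trial design: fold i holds out the i-th trial
# of each class, trains the linear SVM on the remaining 18, and predicts the
# two held-out trials; a decision value of exactly 0 counts incorrect
loo_accuracy <- function(Xa, Xb, C = 1) {
  n <- nrow(Xa)
  correct <- 0L
  for (i in seq_len(n)) {
    Xtr <- rbind(Xa[-i, , drop = FALSE], Xb[-i, , drop = FALSE])
    ytr <- c(rep(1, n - 1), rep(-1, n - 1))
    fit <- cpp_svm_linear(Xtr, ytr, C = C)
    fa <- sum(fit$w * Xa[i, ]) + fit$b
    fb <- sum(fit$w * Xb[i, ]) + fit$b
    correct <- correct + (fa > 0) + (fb < 0)
  }
  100 * correct / (2 * n)
}

#' Single-unit SVM decoding with leave-one-out cross-validation
#'
#' Per repetition, 10 trials per class are sampled without replacement; each
#' of the 10 folds holds out one trial per class, trains a linear SVM
#' (C = 1, no standardization) on the remaining 18 trial rates and predicts
#' the 2 held-out trials. With \code{shuffled = TRUE} the class labels of the
#' 20 selected trials are permuted before cross-validation.
#'
#' @param table A \code{\link{trial_rate_table}} with >= 10 trials per class.
#' @param n_rep Number of repetitions (100).
#' @param n_trials Trials sampled per class (10).
#' @param shuffled Permute labels within each repetition.
#' @param seed Optional seed.
#' @return List of class \code{decoding_result}: \code{scope},
#'   \code{accuracies} (percent, one per repetition), \code{mean_accuracy},
#'   \code{shuffled}.
#' @export
single_unit_decoding <- function(table, n_rep = 100, n_trials = 10,
                                 shuffled = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(table$a) < n_trials || length(table$b) < n_trials)
    stop("fewer than ", n_trials, " trials in a class; unit skipped")
  acc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ra <- sample(table$a, n_trials)
    rb <- sample(table$b, n_trials)
    if (shuffled) {
      pool <- sample(c(ra, rb))
      ra <- pool[seq_len(n_trials)]
      rb <- pool[n_trials + seq_len(n_trials)]
    }
    acc[r] <- loo_accuracy(matrix(ra, ncol = 1), matrix(rb, ncol = 1))
  }
  structure(list(scope = "single_unit", ensemble_size = 1L,
                 accuracies = acc, mean_accuracy = mean(acc),
                 shuffled = shuffled),
            class = "decoding_result")
}

#' Pseudo-population SVM decoding
#'
#' Per repetition, \code{ensemble_size} units are sampled; for each unit 10
#' trials per class are sampled independently, and the i-th sampled trial of
#' every unit is concatenated into one pseudo-trial feature vector.
#' Leave-one-out cross-validation then proceeds as for single units on the
#' 10 + 10 pseudo-trials.
#'
#' @param tables List of \code{\link{trial_rate_table}}s (eligible units,
#'   each with >= 10 trials per class).
#' @param ensemble_size Number of units per pseudo-population.
#' @param n_rep,n_trials,shuffled,seed As in
#'   \code{\link{single_unit_decoding}}.
#' @return A \code{decoding_result}.
#' @export
population_decoding <- function(tables, ensemble_size, n_rep = 100,
                                n_trials = 10, shuffled = FALSE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ensemble_size < 1 || ensemble_size > length(tables))
    stop("ensemble_size must be between 1 and the number of eligible units")
  ok <- vapply(tables, function(tb)
    length(tb$a) >= n_trials && length(tb$b) >= n_trials, logical(1))
  if (!all(ok)) stop("all supplied units must have >= ", n_trials,
                     " trials per class")
  acc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sel <- sample(length(tables), ensemble_size)
    Xa <- vapply(tables[sel], function(tb) sample(tb$a, n_trials),
                 numeric(n_trials))
    Xb <- vapply(tables[sel], function(tb) sample(tb$b, n_trials),
                 numeric(n_trials))
    Xa <- matrix(Xa, nrow = n_trials)
    Xb <- matrix(Xb, nrow = n_trials)
    if (shuffled) {
      pool <- rbind(Xa, Xb)[sample(2 * n_trials), , drop = FALSE]
      Xa <- pool[seq_len(n_trials), , drop = FALSE]
      Xb <- pool[n_trials + seq_len(n_trials), , drop = FALSE]
    }
    acc[r] <- loo_accuracy(Xa, Xb)
  }
  structure(list(scope = "ensemble", ensemble_size = as.integer(ensemble_size),
                 accuracies = acc, mean_accuracy = mean(acc),
                 shuffled = shuffled),
            class = "decoding_result")
}

#' Correct-neuron flag
#'
#' A single unit is a "correct neuron" when its mean decoding accuracy
#' strictly exceeds 55\% (above the 50\% chance level).
#'
#' @param result A single-unit \code{decoding_result}.
#' @param threshold Percent cutoff (55).
#' @return Logical.
#' @export
correct_neuron_flag <- function(result, threshold = 55) {
  result$mean_accuracy > threshold
}

#' Trial tables for a session's two decodable classes
#'
#' @param bundle An \code{\link{experiment_bundle}}.
#' @param events Result of \code{\link{detect_events}}.
#' @param session \code{"EE"} (left vs right) or \code{"SO1"}/\code{"SO2"}
#'   (social vs object).
#' @param unit_ids Units to build tables for (default all).
#' @param min_trials Eligibility threshold per class (10).
#' @return List of \code{trial_rate_table}s for eligible units.
#' @export
session_trial_tables <- function(bundle, events, session, unit_ids = NULL,
                                 min_trials = 10) {
  keys <- if (session == "EE") c("EE.left_empty", "EE.right_empty")
          else paste(session, c("social", "object"), sep = ".")
  iva <- events$sniff[[keys[1]]]
  ivb <- events$sniff[[keys[2]]]
  if (is.null(iva) || is.null(ivb)) stop("missing sniff events for ", session)
  ids <- vapply(bundle$units, `[[`, "", "unit_id")
  if (is.null(unit_ids)) unit_ids <- ids
  tables <- list()
  for (id in unit_ids) {
    u <- bundle$units[[match(id, ids)]]
    tb <- trial_rate_table(u$spikes, iva, ivb, unit_id = id)
    if (length(tb$a) >= min_trials && length(tb$b) >= min_trials)
      tables[[length(tables) + 1]] <- tb
  }
  tables
}
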