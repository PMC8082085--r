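# Sliding-window linear decoding of trial type from population spike
# counts: pseudopopulation construction, cross-validated linear-kernel SVM
# accuracy, and neuron-dropping accuracy time courses.

# counts per trial in an absolute window [t0, t1) relative to an event
window_counts <- function(unit, trials, align_event, lo, hi) {
  ev <- trials[[paste0(align_event, "_s")]]
  st <- unit$spike_times
  # findInterval(x, st, left.open = TRUE) counts spikes strictly before x
  findInterval(ev + hi, st, left.open = TRUE) -
    findInterval(ev + lo, st, left.open = TRUE)
}

#' Build a pseudopopulation trial matrix for one window
#'
#' Units (pooled across sessions) are sampled without replacement; for each
#' unit the correct go and correct no-go trials are resampled with
#' replacement, independently per unit, to `n_pseudotrials` per class —
#' which balances the classes and deliberately destroys within-session
#' noise correlations.
#'
#' Cross-validation separation is enforced at the level of *original*
#' trials: each unit's trials are partitioned into `folds` groups per
#' class, and the pseudotrials of a fold are resampled only from that
#' fold's trials. Resampling without this precaution leaks the per-class
#' empirical distributions into every fold and inflates null decoding
#' accuracy far above chance.
#'
#' @param sessions a [gng_session()] or list of them.
#' @param window `c(lo, hi)` seconds relative to `align_event`.
#' @param align_event alignment event stem.
#' @param n_units units to sample (`NULL` = all available).
#' @param n_pseudotrials pseudotrials per class (rounded up to a multiple
#'   of `folds`).
#' @param folds fold count for the trial-level partition.
#' @param min_trials a unit needs at least this many correct trials per
#'   class to be eligible (must be >= `folds`).
#' @param seed integer seed.
#' @return A `pseudo_trials` list: `x` (matrix `2*n_pseudotrials` x units),
#'   `labels` (factor go/no-go), `foldid`, `window`, `unit_ids`.
#' @export
build_pseudopopulation <- function(sessions, window, align_event = "odor_on",
                                   n_units = NULL, n_pseudotrials = 100L,
                                   folds = 5L, min_trials = max(5L, folds),
                                   seed = 1L) {
  if (inherits(sessions, "gng_session")) sessions <- list(sessions)
  stopifnot(min_trials >= folds)
  pool <- list()
  for (s in sessions) {
    go <- trial_category(s$trials, "correct_go")
    nogo <- trial_category(s$trials, "correct_no_go")
    if (nrow(go) < min_trials || nrow(nogo) < min_trials) next
    for (u in s$units) {
      pool[[length(pool) + 1L]] <- list(
        id = paste0(s$session_id, "/", u$unit_id),
        go = window_counts(u, go, align_event, window[1], window[2]),
        nogo = window_counts(u, nogo, align_event, window[1], window[2]))
    }
  }
  if (is.null(n_units)) n_units <- length(pool)
  if (n_units > length(pool)) {
    stop("n_units exceeds the ", length(pool), " available units",
         call. = FALSE)
  }
  per_fold <- ceiling(n_pseudotrials / folds)
  n_pt <- per_fold * folds
  with_seed(seed, {
    sel <- sample.int(length(pool), n_units)
    x <- matrix(0, nrow = 2L * n_pt, ncol = n_units)
    foldid <- rep(rep(seq_len(folds), each = per_fold), 2L)
    for (j in seq_along(sel)) {
      p <- pool[[sel[j]]]
      col <- numeric(0)
      for (cls in c("go", "nogo")) {
        v <- p[[cls]]
        part <- sample(rep_len(seq_len(folds), length(v)))
        for (f in seq_len(folds)) {
          src <- v[part == f]
          col <- c(col, src[sample.int(length(src), per_fold,
                                       replace = TRUE)])
        }
      }
      x[, j] <- col
    }
    structure(list(x = x,
                   labels = factor(rep(c("go", "no-go"), each = n_pt)),
                   foldid = foldid, window = window,
                   unit_ids = vapply(pool[sel], `[[`, character(1), "id")),
              class = "pseudo_trials")
  })
}

#' Cross-validated linear decoding accuracy
#'
#' Stratified k-fold cross-validation of a linear-kernel support-vector
#' machine (cost fixed at `cost`); features are standardized with
#' training-fold statistics. A `pseudo_trials` object carries its own
#' trial-level fold assignment (see [build_pseudopopulation()]), which is
#' honored so that no original trial informs both a training and a test
#' fold.
#'
#' @param pseudo a `pseudo_trials` object (or a plain matrix with a
#'   `labels` argument).
#' @param labels class labels when `pseudo` is a matrix.
#' @param folds number of folds.
#' @param cost SVM regularization parameter.
#' @param seed integer seed for the fold assignment.
#' @return accuracy fraction in `[0, 1]`.
#' @export
decode_accuracy <- function(pseudo, labels = NULL, folds = 5L, cost = 1,
                            seed = 1L) {
  preset_folds <- NULL
  if (inherits(pseudo, "pseudo_trials")) {
    x <- pseudo$x; labels <- pseudo$labels
    preset_folds <- pseudo$foldid
    folds <- length(unique(preset_folds))
  } else x <- as.matrix(pseudo)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("single-class input", call. = FALSE)
  if (min(table(labels)) < folds) stop("need >= ", folds,
                                       " trials per class", call. = FALSE)
  foldid <- if (!is.null(preset_folds)) preset_folds else with_seed(seed, {
    id <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  correct <- 0L
  for (f in seq_len(folds)) {
    test <- foldid == f
    mu <- colMeans(x[!test, , drop = FALSE])
    sdv <- apply(x[!test, , drop = FALSE], 2, stats::sd)
    keep <- sdv > 0
    if (!any(keep)) {
      # featureless training fold: predict the training majority class
      maj <- names(which.max(table(labels[!test])))
      correct <- correct + sum(labels[test] == maj)
      next
    }
    xt <- scale(x[!test, keep, drop = FALSE], mu[keep], sdv[keep])
    xv <- scale(x[test, keep, drop = FALSE], mu[keep], sdv[keep])
    fit <- e1071::svm(xt, labels[!test], kernel = "linear", cost = cost,
                      scale = FALSE)
    correct <- correct + sum(stats::predict(fit, xv) == labels[test])
  }
  correct / length(labels)
}

#' Sliding-window decoding accuracy across population sizes
#'
#' For each sliding window and each population size, units are resampled
#' `n_resamples` times, a pseudopopulation is built and the
#' cross-validated SVM accuracy recorded. The behavioral accuracy of the
#' analyzed sessions (fraction of correct non-odorless trials) and the 0.5
#' chance level are the reference lines; `min_units_reaching_behavior` is
#' the smallest size whose mean accuracy reaches the behavioral accuracy
#' in a window.
#'
#' @param sessions a [gng_session()] or list of them.
#' @param population_sizes integer vector of unit counts.
#' @param centers window centers (s relative to `align_event`).
#' @param width window width (s).
#' @param align_event alignment event stem.
#' @param n_resamples unit resamples per (window, size).
#' @param n_pseudotrials pseudotrials per class.
#' @param folds,cost decoding parameters.
#' @param seed integer seed.
#' @return A `decoding_curve` data.frame (`bin_center`, `n_units`,
#'   `mean_accuracy`, `sd_accuracy`) with attributes
#'   `behavioral_accuracy`, `chance` (0.5) and
#'   `min_units_reaching_behavior` (named by window center, `NA` if none).
#' @export
decoding_timecourse <- function(sessions,
                                population_sizes = c(1L, 5L, 10L, 25L,
                                                     50L, 100L),
                                centers = seq(-0.2, 0.7, by = 0.05),
                                width = 0.100, align_event = "odor_on",
                                n_resamples = 20L, n_pseudotrials = 100L,
                                folds = 5L, cost = 1, seed = 1L) {
  if (inherits(sessions, "gng_session")) sessions <- list(sessions)
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  scored <- trials[trials$odor_kind != "odorless", ]
  behav <- mean(scored$outcome == "correct")
  rows <- list()
  for (ci in seq_along(centers)) {
    win <- centers[ci] + c(-width / 2, width / 2)
    for (si in seq_along(population_sizes)) {
      size <- population_sizes[si]
      acc <- vapply(seq_len(n_resamples), function(r) {
        s_r <- child_seed(seed, ci * 10000L + si * 100L + r)
        pp <- build_pseudopopulation(sessions, win, align_event,
                                     n_units = size,
                                     n_pseudotrials = n_pseudotrials,
                                     seed = s_r)
        decode_accuracy(pp, folds = folds, cost = cost,
                        seed = child_seed(s_r, 1L))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        bin_center = centers[ci], n_units = size,
        mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc))
    }
  }
  out <- do.call(rbind, rows)
  min_units <- vapply(centers, function(ct) {
    sub <- out[out$bin_center == ct, ]
    ok <- sub$n_units[sub$mean_accuracy >= behav]
    if (length(ok)) min(ok) else NA_real_
  }, numeric(1))
  names(min_units) <- signif(centers, 8)
  structure(out, behavioral_accuracy = behav, chance = 0.5,
            min_units_reaching_behavior = min_units,
            class = c("decoding_curve", "data.frame"))
}
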