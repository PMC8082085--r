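# Sliding-bin auROC traces (width 100 ms, step 20 ms) and the derived
# temporal measures, plus peak/half-width, alignment contrasts, condition
# contrasts, across-trial stability and significant-proportion time courses.

#' Sliding-bin auROC trace for one unit
#'
#' For each sliding bin (default width 100 ms, step 20 ms) the per-trial
#' rate in the bin is compared against the per-trial short-baseline rate
#' (200–0 ms before ITI end) — or, for `condition = "go_vs_nogo"`, go-trial
#' bin rates against no-go-trial bin rates — by auROC with a permutation
#' test. With `clip_to_port_exit = TRUE` (appropriate for odor-onset
#' alignment) a trial contributes to a bin only when the whole bin lies
#' before its odor-port exit, so bins use only within-trial data.
#'
#' @param unit a [spike_train()].
#' @param session a [gng_session()] (correct trials of the relevant
#'   categories are selected internally).
#' @param condition `"go_vs_baseline"`, `"nogo_vs_baseline"` or
#'   `"go_vs_nogo"`.
#' @param align_event event stem the bins are aligned to.
#' @param window `c(start, end)` seconds relative to the event covered by
#'   bin centers' spans.
#' @param width,step sliding-bin width and step (s).
#' @param n_perm,alpha permutation test parameters.
#' @param seed optional seed (fanned out per bin).
#' @param min_trials minimum trials on each side for a bin to be evaluated.
#' @param min_consecutive consecutive significant bins required to call an
#'   onset.
#' @param clip_to_port_exit drop a trial from bins ending after its
#'   port exit.
#' @return An `auroc_trace` data.frame (`bin_center`, `auroc`, `p_value`,
#'   `n_a`, `n_b`, `significant`, `direction`) with attributes `onset_time`,
#'   `center_of_mass`, `duration`, `condition`, `align_event`, `width`,
#'   `step`, `unit_id`.
#' @export
sliding_auroc <- function(unit, session,
                          condition = c("go_vs_baseline", "nogo_vs_baseline",
                                        "go_vs_nogo"),
                          align_event = "odor_on", window = c(-0.1, 1.0),
                          width = 0.100, step = 0.020,
                          n_perm = 1000L, alpha = 0.01, seed = NULL,
                          min_trials = 5L, min_consecutive = 3L,
                          clip_to_port_exit = align_event == "odor_on") {
  condition <- match.arg(condition)
  trials_a <- trial_category(session$trials,
                             if (condition == "nogo_vs_baseline")
                               "correct_no_go" else "correct_go")
  trials_b <- switch(condition,
                     go_vs_nogo = trial_category(session$trials,
                                                 "correct_no_go"),
                     NULL)
  sliding_auroc_trials(unit, trials_a, trials_b, align_event, window,
                       width, step, n_perm, alpha, seed, min_trials,
                       min_consecutive, clip_to_port_exit,
                       condition = condition)
}

# Worker on explicit trial tables; trials_b = NULL means "versus the
# short-baseline rates of trials_a".
sliding_auroc_trials <- function(unit, trials_a, trials_b = NULL,
                                 align_event = "odor_on",
                                 window = c(-0.1, 1.0), width = 0.100,
                                 step = 0.020, n_perm = 1000L, alpha = 0.01,
                                 seed = NULL, min_trials = 5L,
                                 min_consecutive = 3L,
                                 clip_to_port_exit = FALSE,
                                 condition = "custom") {
  centers <- seq(window[1] + width / 2, window[2] - width / 2 + 1e-9,
                 by = step)
  st <- unit$spike_times
  bin_rates <- function(trials, center) {
    ev <- trials[[paste0(align_event, "_s")]]
    lo <- ev + center - width / 2
    hi <- ev + center + width / 2
    keep <- if (clip_to_port_exit) hi <= trials$port_exit_s + 1e-9
            else rep(TRUE, length(ev))
    (findInterval(hi[keep], st, left.open = TRUE) -
       findInterval(lo[keep], st, left.open = TRUE)) / width
  }
  base_a <- if (is.null(trials_b)) {
    epoch_rates(unit, trials_a, "baseline_short")
  } else NULL
  rows <- vector("list", length(centers))
  for (k in seq_along(centers)) {
    ev <- trials_a[[paste0(align_event, "_s")]]
    keep_a <- if (clip_to_port_exit) {
      ev + centers[k] + width / 2 <= trials_a$port_exit_s + 1e-9
    } else rep(TRUE, nrow(trials_a))
    a <- bin_rates(trials_a, centers[k])
    b <- if (is.null(trials_b)) base_a[keep_a] else bin_rates(trials_b,
                                                              centers[k])
    if (length(a) < min_trials || length(b) < min_trials) {
      rows[[k]] <- data.frame(bin_center = centers[k], auroc = NA_real_,
                              p_value = NA_real_, n_a = length(a),
                              n_b = length(b), significant = FALSE,
                              direction = "none")
      next
    }
    res <- auroc_test(a, b, n_perm = n_perm, alpha = alpha,
                      seed = if (is.null(seed)) NULL else child_seed(seed, k))
    rows[[k]] <- data.frame(bin_center = centers[k], auroc = res$auroc,
                            p_value = res$p_value, n_a = res$n_a,
                            n_b = res$n_b,
                            significant = res$direction != "none",
                            direction = res$direction)
  }
  trace <- do.call(rbind, rows)
  m <- trace_measures(trace, width = width, min_consecutive = min_consecutive)
  structure(trace, onset_time = m$onset_time,
            center_of_mass = m$center_of_mass, duration = m$duration,
            condition = condition, align_event = align_event,
            width = width, step = step, unit_id = unit$unit_id,
            class = c("auroc_trace", "data.frame"))
}

#' Temporal measures of a sliding auROC trace
#'
#' \describe{
#'   \item{onset_time}{left edge of the first bin of the first run of at
#'     least `min_consecutive` consecutive significant bins (`NA` if no
#'     such run).}
#'   \item{center_of_mass}{`sum(t * |auROC - 0.5|) / sum(|auROC - 0.5|)`
#'     over significant bins (`NA` if none).}
#'   \item{duration}{total time covered by the union of the significant
#'     bins' spans; 0 when no bin is significant.}
#' }
#'
#' @param trace data.frame with `bin_center`, `auroc`, `significant`.
#' @param width bin width (s).
#' @param min_consecutive run length required for an onset.
#' @return list with `onset_time`, `center_of_mass`, `duration`.
#' @export
trace_measures <- function(trace, width = 0.100, min_consecutive = 3L) {
  sig <- which(!is.na(trace$significant) & trace$significant)
  if (!length(sig)) {
    return(list(onset_time = NA_real_, center_of_mass = NA_real_,
                duration = 0))
  }
  runs <- rle(!is.na(trace$significant) & trace$significant)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  long <- runs$values & runs$lengths >= min_consecutive
  onset <- if (any(long)) {
    trace$bin_center[starts[which(long)[1L]]] - width / 2
  } else NA_real_
  w <- abs(trace$auroc[sig] - 0.5)
  com <- if (sum(w) > 0) sum(trace$bin_center[sig] * w) / sum(w) else
    mean(trace$bin_center[sig])
  # union length of the (possibly overlapping) significant bin intervals
  lo <- trace$bin_center[sig] - width / 2
  hi <- trace$bin_center[sig] + width / 2
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  dur <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
    else { dur <- dur + cur_hi - cur_lo; cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  dur <- dur + cur_hi - cur_lo
  list(onset_time = onset, center_of_mass = com, duration = dur)
}

#' Compare excitation and suppression response durations
#'
#' Two-sided Wilcoxon rank-sum test between two sets of response durations
#' (seconds), as used to contrast sharp excitations with persistent
#' suppressions.
#'
#' @param excitation_durations,suppression_durations non-empty numeric
#'   vectors.
#' @return list: `p_value`, `statistic`, `median_excitation`,
#'   `median_suppression`.
#' @export
compare_durations <- function(excitation_durations, suppression_durations) {
  stopifnot(length(excitation_durations) > 0,
            length(suppression_durations) > 0)
  if (length(excitation_durations) < 3 || length(suppression_durations) < 3) {
    warning("fewer than 3 durations on one side; exact test", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(excitation_durations,
                                            suppression_durations,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_excitation = stats::median(excitation_durations),
       median_suppression = stats::median(suppression_durations))
}

#' Peak rate and temporal half-width of a PSTH
#'
#' The peak is the maximum of the trial-averaged smoothed rate; the
#' half-width is the contiguous time span around the peak over which the
#' rate stays at or above `baseline + (peak - baseline) / 2`, with linear
#' interpolation at the crossings.
#'
#' @param psth a `smoothed_psth` object (trials x bins).
#' @param baseline_rate reference rate (Hz) the peak is measured against.
#' @return list: `peak_rate`, `peak_time`, `half_width` (`NA` when the
#'   PSTH never exceeds the baseline).
#' @export
peak_and_halfwidth <- function(psth, baseline_rate = 0) {
  avg <- colMeans(unclass(psth))
  centers <- attr(psth, "bin_centers")
  stopifnot(length(avg) > 0)
  i_pk <- which.max(avg)
  peak <- avg[i_pk]
  if (!(peak > baseline_rate)) {
    return(list(peak_rate = peak, peak_time = centers[i_pk],
                half_width = NA_real_))
  }
  thr <- baseline_rate + (peak - baseline_rate) / 2
  cross_left <- centers[1]
  for (i in seq(i_pk, 2)) {
    if (avg[i - 1] < thr) {
      cross_left <- centers[i - 1] + (centers[i] - centers[i - 1]) *
        (thr - avg[i - 1]) / (avg[i] - avg[i - 1])
      break
    }
  }
  cross_right <- centers[length(centers)]
  if (i_pk < length(avg)) {
    for (i in seq(i_pk, length(avg) - 1)) {
      if (avg[i + 1] < thr) {
        cross_right <- centers[i] + (centers[i + 1] - centers[i]) *
          (avg[i] - thr) / (avg[i] - avg[i + 1])
        break
      }
    }
  }
  list(peak_rate = unname(peak), peak_time = unname(centers[i_pk]),
       half_width = unname(cross_right - cross_left))
}

#' Compare response peaks between odor-onset and port-exit alignment
#'
#' For each unit, the correct-go-trial PSTH is computed aligned to odor
#' onset and to odor-port exit; peak rates and half-widths are compared
#' across units with paired Wilcoxon signed-rank tests. Higher onset-aligned
#' peaks with narrower half-widths indicate responses locked to the odor,
#' not to the movement.
#'
#' @param units list of [spike_train()]s (typically the go-cue responsive
#'   units).
#' @param session a [gng_session()].
#' @param onset_window,exit_window PSTH windows `c(pre, post)` for the two
#'   alignments.
#' @param kernel_sd smoothing kernel SD (s).
#' @return list: per-unit data.frame `measures`, and `p_peak`,
#'   `p_half_width` (signed-rank p values; `NA` with a warning when fewer
#'   than 10 units are supplied).
#' @export
alignment_comparison <- function(units, session,
                                 onset_window = c(0.1, 1.0),
                                 exit_window = c(1.0, 0.3),
                                 kernel_sd = 0.060) {
  go <- trial_category(session$trials, "correct_go")
  rows <- lapply(units, function(u) {
    ps_on <- smooth_psth(align_and_bin(u, go, "odor_on", onset_window),
                         kernel_sd)
    ps_ex <- smooth_psth(align_and_bin(u, go, "port_exit", exit_window),
                         kernel_sd)
    m_on <- peak_and_halfwidth(ps_on)
    m_ex <- peak_and_halfwidth(ps_ex)
    data.frame(unit_id = u$unit_id,
               peak_onset = m_on$peak_rate, hw_onset = m_on$half_width,
               peak_exit = m_ex$peak_rate, hw_exit = m_ex$half_width)
  })
  df <- do.call(rbind, rows)
  if (nrow(df) < 10) {
    warning("fewer than 10 units; paired tests underpowered", call. = FALSE)
  }
  test <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) return(NA_real_)
    if (all(abs(x[ok] - y[ok]) < 1e-12)) return(1)  # identical alignments
    suppressWarnings(stats::wilcox.test(x[ok], y[ok], paired = TRUE))$p.value
  }
  list(measures = df,
       p_peak = test(df$peak_onset, df$peak_exit),
       p_half_width = test(df$hw_onset, df$hw_exit))
}

#' Cue response contrast across trial categories
#'
#' Odor-sampling-epoch versus long-baseline auROC per behavioral category
#' (correct go, correct no-go, error, odorless). Categories with fewer than
#' `min_trials` trials are omitted and listed in `skipped`.
#'
#' @param unit a [spike_train()].
#' @param session a [gng_session()].
#' @param categories categories to include.
#' @param min_trials minimum trials per category.
#' @inheritParams auroc_test
#' @return list of `auroc_result`s by category, with attribute `skipped`.
#' @export
condition_contrast <- function(unit, session,
                               categories = c("correct_go", "correct_no_go",
                                              "error", "odorless"),
                               min_trials = 5L, n_perm = 1000L,
                               alpha = 0.01, seed = NULL) {
  out <- list()
  skipped <- character(0)
  for (i in seq_along(categories)) {
    cat_i <- categories[i]
    tr <- trial_category(session$trials, cat_i)
    if (nrow(tr) < min_trials) {
      skipped <- c(skipped, cat_i)
      next
    }
    out[[cat_i]] <- auroc_test(
      epoch_rates(unit, tr, "odor_sampling"),
      epoch_rates(unit, tr, "baseline_long"),
      n_perm = n_perm, alpha = alpha,
      seed = if (is.null(seed)) NULL else child_seed(seed, i))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Across-trial stability of a cue response
#'
#' Spearman rank correlation between per-trial odor-sampling rates and
#' trial index; a response is called stable when the correlation is not
#' significant at 0.05.
#'
#' @param unit a [spike_train()].
#' @param trials trial table rows (chronological order), at least 20.
#' @return list: `rho`, `p_value`, `slope` (Hz per trial, least squares),
#'   `stable`.
#' @export
trial_stability <- function(unit, trials) {
  if (nrow(trials) < 20) stop("need at least 20 trials", call. = FALSE)
  r <- epoch_rates(unit, trials, "odor_sampling")
  idx <- seq_along(r)
  slope <- unname(stats::coef(stats::lm(r ~ idx))[2])
  if (stats::sd(r) == 0) {
    return(list(rho = 0, p_value = 1, slope = 0, stable = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(r, idx, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, slope = slope,
       stable = ct$p.value >= 0.05)
}

#' Per-type fractions of significantly responding units over time
#'
#' For each classified unit, a sliding auROC trace versus the short
#' baseline is computed on the requested trial category and alignment
#' event(s); per neuron type, bin and direction, the fraction of units
#' whose bin is significantly excited or suppressed is returned.
#'
#' @param session a [gng_session()].
#' @param classifications data.frame from [classify_session()].
#' @param category trial category supplying the trials.
#' @param align_events character vector of event stems.
#' @param window window around each event.
#' @param ... forwarded to the sliding trace (`width`, `step`, `n_perm`,
#'   `alpha`, `seed`, `min_trials`).
#' @return data.frame: `align_event`, `type_label`, `bin_center`,
#'   `frac_excitation`, `frac_suppression`, `n_units`.
#' @export
significant_proportion_timecourse <- function(session, classifications,
                                              category = "correct_go",
                                              align_events = "port_exit",
                                              window = c(-0.5, 1.0), ...) {
  cl <- classifications[classifications$classifiable, , drop = FALSE]
  trials <- trial_category(session$trials, category)
  out <- list()
  for (ev in align_events) {
    traces <- lapply(cl$unit_id, function(id) {
      sliding_auroc_trials(session$units[[id]], trials, NULL,
                           align_event = ev, window = window,
                           clip_to_port_exit = FALSE, ...)
    })
    centers <- traces[[1]]$bin_center
    for (tp in unique(cl$type_label)) {
      sel <- which(cl$type_label == tp)
      exc <- sapply(traces[sel], function(tr) tr$direction == "excitation")
      sup <- sapply(traces[sel], function(tr) tr$direction == "suppression")
      exc <- matrix(exc, nrow = length(centers))
      sup <- matrix(sup, nrow = length(centers))
      out[[length(out) + 1L]] <- data.frame(
        align_event = ev, type_label = tp, bin_center = centers,
        frac_excitation = rowMeans(exc), frac_suppression = rowMeans(sup),
        n_units = length(sel))
    }
  }
  do.call(rbind, out)
}
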