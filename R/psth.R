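# Event-aligned binning, Gaussian smoothing and per-trial epoch rates:
# the shared numerical substrate for every response statistic.

#' Align spikes to a trial event and bin them
#'
#' Bins are half-open `[lo, hi)`; a spike exactly on an edge falls in the
#' later bin. Bin 1 starts at `-window[1]` relative to the event.
#'
#' @param unit a [spike_train()].
#' @param trials session trial table (already filtered to the trials of
#'   interest).
#' @param event_name event column stem, e.g. `"odor_on"`, `"port_exit"`,
#'   `"water_on"`.
#' @param window `c(pre, post)` seconds around the event (both >= 0,
#'   `pre + post > 0`).
#' @param bin_width bin width in seconds (default 20 ms).
#' @param drop_missing drop trials lacking the event instead of erroring;
#'   the number dropped is recorded in attribute `n_dropped`.
#' @return An `aligned_counts` object: integer matrix trials x bins with
#'   attributes `bin_centers`, `bin_width`, `window`, `align_event`,
#'   `trial_ids`.
#' @export
align_and_bin <- function(unit, trials, event_name, window,
                          bin_width = 0.020, drop_missing = FALSE) {
  stopifnot(inherits(unit, "spike_train"), length(window) == 2L,
            bin_width > 0)
  if (sum(window) <= 0) stop("window must have positive total length",
                             call. = FALSE)
  col <- paste0(event_name, "_s")
  if (!col %in% names(trials)) stop("unknown event: ", event_name,
                                    call. = FALSE)
  ev <- trials[[col]]
  n_dropped <- sum(is.na(ev))
  if (n_dropped > 0L) {
    if (!drop_missing) {
      stop("event '", event_name, "' missing on ", n_dropped, " trial(s)",
           call. = FALSE)
    }
    trials <- trials[!is.na(ev), , drop = FALSE]
    ev <- ev[!is.na(ev)]
  }
  n_bins <- floor((window[1] + window[2]) / bin_width + 1e-9)
  edges <- -window[1] + bin_width * (0:n_bins)
  counts <- matrix(0L, nrow = length(ev), ncol = n_bins)
  st <- unit$spike_times
  for (i in seq_along(ev)) {
    rel <- st[st >= ev[i] + edges[1] & st < ev[i] + edges[n_bins + 1L]] - ev[i]
    if (length(rel)) {
      idx <- findInterval(rel, edges, left.open = FALSE)
      counts[i, ] <- tabulate(idx, nbins = n_bins)
    }
  }
  structure(counts,
            bin_centers = edges[-length(edges)] + bin_width / 2,
            bin_width = bin_width, window = window,
            align_event = event_name,
            trial_ids = trials$trial_id, n_dropped = n_dropped,
            class = c("aligned_counts", "matrix"))
}

gaussian_smoothing_matrix <- function(n_bins, bin_width, kernel_sd) {
  centers <- seq_len(n_bins)
  half <- ceiling(4 * kernel_sd / bin_width)
  d <- outer(centers, centers, "-") * bin_width
  w <- exp(-d^2 / (2 * kernel_sd^2))
  w[abs(d) > half * bin_width] <- 0
  # truncated-kernel renormalization: each output bin averages over the
  # in-window part of the kernel, avoiding edge rate suppression
  sweep(w, 2, colSums(w), "/")
}

#' Smooth aligned counts into a firing-rate PSTH
#'
#' Converts counts to rates (Hz) and convolves each trial with a Gaussian
#' kernel, renormalizing the truncated kernel at the window edges.
#'
#' @param counts an `aligned_counts` object.
#' @param kernel_sd Gaussian kernel SD in seconds (default 60 ms).
#' @return A `smoothed_psth` object: matrix trials x bins of rates (Hz)
#'   carrying the same alignment attributes plus `kernel_sd`.
#' @export
smooth_psth <- function(counts, kernel_sd = 0.060) {
  stopifnot(inherits(counts, "aligned_counts"))
  w <- attr(counts, "bin_width")
  if (w >= kernel_sd) stop("bin_width must be smaller than kernel_sd",
                           call. = FALSE)
  rates <- unclass(counts) / w
  sm <- rates %*% gaussian_smoothing_matrix(ncol(counts), w, kernel_sd)
  structure(sm,
            bin_centers = attr(counts, "bin_centers"), bin_width = w,
            window = attr(counts, "window"),
            align_event = attr(counts, "align_event"),
            trial_ids = attr(counts, "trial_ids"),
            kernel_sd = kernel_sd,
            class = c("smoothed_psth", "matrix"))
}

#' Trial-averaged PSTH
#' @param psth a `smoothed_psth` (or `aligned_counts`) object.
#' @return numeric vector of mean rate (or count) per bin, named by bin
#'   center.
#' @export
psth_average <- function(psth) {
  out <- colMeans(unclass(psth))
  names(out) <- signif(attr(psth, "bin_centers"), 8)
  out
}

#' Per-trial firing rate within a named epoch
#'
#' @param unit a [spike_train()].
#' @param trials trial table rows to evaluate.
#' @param epoch_name epoch passed to [epoch_bounds()].
#' @param ... forwarded to [epoch_bounds()].
#' @return numeric vector, one rate (Hz) per trial.
#' @export
epoch_rates <- function(unit, trials, epoch_name, ...) {
  stopifnot(inherits(unit, "spike_train"))
  st <- unit$spike_times
  bounds <- vapply(seq_len(nrow(trials)),
                   function(i) epoch_bounds(trials[i, ], epoch_name, ...),
                   numeric(2))
  (findInterval(bounds[2, ], st, left.open = TRUE) -
     findInterval(bounds[1, ], st, left.open = TRUE)) /
    (bounds[2, ] - bounds[1, ])
}

#' Event-aligned histogram series
#'
#' Smoothed PSTH segments aligned to a sequence of trial events, kept as
#' separate segments (explicit breaks) because latencies between events vary
#' across trials. Trials lacking an event are excluded from that segment.
#'
#' @param unit a [spike_train()].
#' @param trials trial table rows.
#' @param events named list: for each event name, `c(pre, post)` window.
#' @param bin_width,kernel_sd binning and smoothing parameters.
#' @return A `psth_series`: list of per-event `smoothed_psth` objects, with
#'   per-segment excluded-trial counts in attribute `n_excluded`.
#' @export
event_aligned_histogram_series <- function(unit, trials, events,
                                           bin_width = 0.020,
                                           kernel_sd = 0.060) {
  stopifnot(is.list(events), length(names(events)) == length(events))
  n_excluded <- integer(length(events))
  segs <- vector("list", length(events))
  for (i in seq_along(events)) {
    ac <- align_and_bin(unit, trials, names(events)[i], events[[i]],
                        bin_width, drop_missing = TRUE)
    n_excluded[i] <- attr(ac, "n_dropped")
    segs[[i]] <- smooth_psth(ac, kernel_sd)
  }
  names(segs) <- names(events)
  names(n_excluded) <- names(events)
  if (any(n_excluded > 0L)) {
    warning(sum(n_excluded), " trial-segment(s) excluded for missing events",
            call. = FALSE)
  }
  structure(segs, n_excluded = n_excluded, class = "psth_series")
}
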