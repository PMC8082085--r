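# Canonical time conventions used throughout the package:
#  * all event times are seconds on the session clock (zero at session start);
#  * events are instants, epochs are half-open intervals [start, end);
#  * odor valve opening and odor port entry are one timestamp (`odor_on`).

TRIAL_COLUMNS <- c("trial_id", "trial_type", "outcome", "odor_kind",
                   "iti_end_s", "odor_on_s", "odor_off_s", "port_exit_s",
                   "water_entry_s", "water_on_s")

#' Construct a unit spike train
#'
#' @param unit_id character scalar identifier.
#' @param spike_times numeric vector of spike timestamps (seconds, session
#'   clock). Must be finite, non-negative and non-decreasing unless
#'   `sort = TRUE`.
#' @param sort sort the spike times instead of rejecting unsorted input.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, sort = FALSE) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L)
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times) || any(!is.finite(spike_times))) {
    stop("unit '", unit_id, "': spike times must be finite", call. = FALSE)
  }
  if (any(spike_times < 0)) {
    stop("unit '", unit_id, "': spike times must be >= 0", call. = FALSE)
  }
  if (is.unsorted(spike_times)) {
    if (sort) spike_times <- sort(spike_times)
    else stop("unit '", unit_id, "': spike times must be non-decreasing",
              call. = FALSE)
  }
  structure(list(unit_id = unit_id, spike_times = spike_times),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", x$unit_id, "-", length(x$spike_times), "spikes\n")
  invisible(x)
}

#' Assemble and validate a recording session
#'
#' A session couples per-unit spike trains with a per-trial behavioral event
#' table. Trial events must satisfy the task ordering
#' `iti_end <= odor_on < odor_off <= port_exit`, water events are present
#' exactly when go behavior was executed (correct go, or a no-go error in
#' which the animal moved to the water port), and trials must be strictly
#' ordered in time.
#'
#' @param session_id character scalar.
#' @param units list of [spike_train()] objects.
#' @param trials data.frame with columns `trial_id`, `trial_type`
#'   (`"go"`/`"no-go"`), `outcome` (`"correct"`/`"error"`), `odor_kind`
#'   (`"go-cue"`/`"no-go-cue"`/`"odorless"`), `iti_end_s`, `odor_on_s`,
#'   `odor_off_s`, `port_exit_s`, `water_entry_s`, `water_on_s`
#'   (`NA` = absent).
#' @param meta named list of free-form metadata.
#' @return An object of class `gng_session`.
#' @export
gng_session <- function(session_id, units, trials, meta = list()) {
  stopifnot(is.character(session_id), length(session_id) == 1L)
  if (length(units) < 1L) stop("session needs at least one unit", call. = FALSE)
  if (!all(vapply(units, inherits, logical(1), "spike_train"))) {
    stop("units must be a list of spike_train objects", call. = FALSE)
  }
  names(units) <- vapply(units, `[[`, character(1), "unit_id")
  if (anyDuplicated(names(units))) stop("duplicate unit_id", call. = FALSE)
  trials <- as.data.frame(trials)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("trials table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) < 1L) stop("session needs at least one trial", call. = FALSE)
  validate_trials(trials)
  structure(list(session_id = session_id, units = units,
                 trials = trials[TRIAL_COLUMNS], meta = meta),
            class = "gng_session")
}

validate_trials <- function(trials) {
  ok_type <- trials$trial_type %in% c("go", "no-go")
  if (!all(ok_type)) {
    stop("trial ", trials$trial_id[!ok_type][1L], ": bad trial_type",
         call. = FALSE)
  }
  ok_out <- trials$outcome %in% c("correct", "error")
  if (!all(ok_out)) {
    stop("trial ", trials$trial_id[!ok_out][1L], ": bad outcome",
         call. = FALSE)
  }
  ok_odor <- trials$odor_kind %in% c("go-cue", "no-go-cue", "odorless")
  if (!all(ok_odor)) {
    stop("trial ", trials$trial_id[!ok_odor][1L], ": bad odor_kind",
         call. = FALSE)
  }
  for (tt in seq_len(nrow(trials))) {
    tr <- trials[tt, ]
    with(tr, {
      if (!(iti_end_s <= odor_on_s && odor_on_s < odor_off_s &&
            odor_off_s <= port_exit_s)) {
        stop("trial ", trial_id,
             ": event ordering violated (need iti_end <= odor_on < odor_off",
             " <= port_exit)", call. = FALSE)
      }
    })
    go_executed <- (tr$trial_type == "go" && tr$outcome == "correct") ||
      (tr$trial_type == "no-go" && tr$outcome == "error")
    if (go_executed && is.na(tr$water_entry_s)) {
      stop("trial ", tr$trial_id, ": go behavior executed but water_entry_s",
           " absent", call. = FALSE)
    }
    if (!go_executed && (!is.na(tr$water_entry_s) || !is.na(tr$water_on_s))) {
      stop("trial ", tr$trial_id, ": water events present without go behavior",
           call. = FALSE)
    }
    if (!is.na(tr$water_entry_s) && tr$water_entry_s < tr$port_exit_s) {
      stop("trial ", tr$trial_id, ": water_entry before port_exit",
           call. = FALSE)
    }
    if (!is.na(tr$water_on_s) &&
        (is.na(tr$water_entry_s) || tr$water_on_s < tr$water_entry_s)) {
      stop("trial ", tr$trial_id, ": water_on before water_entry",
           call. = FALSE)
    }
  }
  # trials strictly ordered in time with no interleaving
  ends <- pmax(trials$port_exit_s, trials$water_on_s, trials$water_entry_s,
               na.rm = TRUE)
  if (nrow(trials) > 1L &&
      any(trials$iti_end_s[-1L] < ends[-nrow(trials)])) {
    stop("trials overlap in time", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gng_session <- function(x, ...) {
  cat("<gng_session>", x$session_id, "-", length(x$units), "units,",
      nrow(x$trials), "trials\n")
  invisible(x)
}

#' Read a session from a plain-text session directory
#'
#' The directory holds `units.csv` (`unit_id`, `spike_time_s`), `trials.csv`
#' (see [gng_session()]; empty cells mean the event is absent) and
#' `meta.json`.
#'
#' @param path directory path.
#' @param sort_spikes sort unsorted spike times on load instead of erroring.
#' @return A validated [gng_session()].
#' @export
load_session <- function(path, sort_spikes = FALSE) {
  for (f in c("units.csv", "trials.csv", "meta.json")) {
    if (!file.exists(file.path(path, f))) {
      stop("session directory missing file: ", f, call. = FALSE)
    }
  }
  u <- utils::read.csv(file.path(path, "units.csv"),
                       colClasses = c(unit_id = "character",
                                      spike_time_s = "numeric"))
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            colClasses = c(trial_id = "integer",
                                           trial_type = "character",
                                           outcome = "character",
                                           odor_kind = "character"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  unit_ids <- unique(u$unit_id)
  units <- lapply(unit_ids, function(id) {
    spike_train(id, u$spike_time_s[u$unit_id == id], sort = sort_spikes)
  })
  # units listed in meta with zero spikes survive the round trip
  extra <- setdiff(unlist(meta$unit_ids), unit_ids)
  units <- c(units, lapply(extra, function(id) spike_train(id, numeric(0))))
  sid <- if (!is.null(meta$session_id)) meta$session_id else basename(path)
  gng_session(sid, units, trials, meta = meta)
}

#' Write a session to a plain-text session directory
#'
#' Timestamps are written with microsecond precision so that
#' `load_session(write_session(s))` reproduces `s` to within 1e-6 s.
#'
#' @param session a [gng_session()].
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "gng_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path,
                              call. = FALSE)
  u <- data.frame(
    unit_id = rep(names(session$units),
                  vapply(session$units, function(x) length(x$spike_times),
                         integer(1))),
    spike_time_s = sprintf("%.6f", unlist(lapply(session$units,
                                                 `[[`, "spike_times"))))
  utils::write.csv(u, file.path(path, "units.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- session$trials
  num <- vapply(tr, is.numeric, logical(1)) & names(tr) != "trial_id"
  tr[num] <- lapply(tr[num], function(x) ifelse(is.na(x), "",
                                                sprintf("%.6f", x)))
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- session$meta
  meta$session_id <- session$session_id
  meta$unit_ids <- names(session$units)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Epoch boundaries for one trial
#'
#' Named analysis epochs, all half-open `[start, end)`:
#' \describe{
#'   \item{baseline_long}{1000–0 ms before the end of the inter-trial
#'     interval; used by the five-type classification.}
#'   \item{baseline_short}{200–0 ms before ITI end; used by sliding-bin
#'     auROC traces.}
#'   \item{odor_sampling}{odor valve opening until odor-port exit.}
#'   \item{drinking}{from water onset, `drink_dur` seconds (go behavior
#'     only).}
#'   \item{no_go_waiting}{from odor-port exit, `wait_dur` seconds (correct
#'     no-go trials only).}
#' }
#'
#' @param trial one-row data.frame from a session trial table.
#' @param epoch_name one of the names above.
#' @param drink_dur,wait_dur epoch lengths (s) for the post-behavior epochs.
#' @return numeric `c(start, end)` in seconds.
#' @export
epoch_bounds <- function(trial, epoch_name, drink_dur = 1.0, wait_dur = 1.0) {
  stopifnot(nrow(trial) == 1L)
  out <- switch(
    epoch_name,
    baseline_long = c(trial$iti_end_s - 1.0, trial$iti_end_s),
    baseline_short = c(trial$iti_end_s - 0.2, trial$iti_end_s),
    odor_sampling = c(trial$odor_on_s, trial$port_exit_s),
    drinking = {
      if (is.na(trial$water_on_s)) {
        stop("drinking epoch undefined: no water onset on trial ",
             trial$trial_id, call. = FALSE)
      }
      c(trial$water_on_s, trial$water_on_s + drink_dur)
    },
    no_go_waiting = {
      if (trial$trial_type != "no-go" || trial$outcome != "correct") {
        stop("no_go_waiting epoch undefined on trial ", trial$trial_id,
             call. = FALSE)
      }
      c(trial$port_exit_s, trial$port_exit_s + wait_dur)
    },
    stop("unknown epoch: ", epoch_name, call. = FALSE)
  )
  if (!(out[1] < out[2])) stop("degenerate epoch on trial ", trial$trial_id,
                               call. = FALSE)
  out
}

#' Select trials by behavioral category
#'
#' @param trials session trial table.
#' @param category one of `"correct_go"`, `"correct_no_go"`, `"error"`,
#'   `"odorless"`, `"all"`.
#' @return subset of the trial table.
#' @export
trial_category <- function(trials, category = c("correct_go", "correct_no_go",
                                                "error", "odorless", "all")) {
  category <- match.arg(category)
  keep <- switch(category,
    correct_go = trials$trial_type == "go" & trials$outcome == "correct" &
      trials$odor_kind == "go-cue",
    correct_no_go = trials$trial_type == "no-go" & trials$outcome == "correct" &
      trials$odor_kind == "no-go-cue",
    error = trials$outcome == "error" & trials$odor_kind != "odorless",
    odorless = trials$odor_kind == "odorless",
    all = rep(TRUE, nrow(trials)))
  trials[keep, , drop = FALSE]
}
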