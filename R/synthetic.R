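# Seeded synthetic go/no-go sessions with ground-truth neuron archetypes.
#
# The generator emulates the statistical structure the downstream analyses
# assume: log-normal baseline rates, five response archetypes in realistic
# proportions, odor-sampling durations with the task's printed medians/IQRs,
# and spikes drawn from an inhomogeneous Poisson process by thinning.

#' Evaluate an expression with a private RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a parent seed
#'
#' Counter-based fan-out so each pipeline stage / unit gets an independent,
#' reproducible stream. Kept below 2^31.
#' @param seed parent integer seed.
#' @param index non-negative counter.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}

#' Generator configuration
#'
#' Defaults encode the study conditions the simulator emulates: 100 units,
#' 200 trials, five archetypes at proportions 38.9/5.8/11.5/17.0/26.8%,
#' behavioral accuracy 90% (the task criterion is >80%), log-normal baseline
#' rates with median 0.90 Hz and IQR 0.23–3.07 Hz, and odor-sampling
#' durations with median (IQR) 788 (669–962) ms on go trials and
#' 642 (562–798) ms on no-go trials, clipped below at the 0.5 s odor
#' presentation the animal must sit through.
#'
#' @param n_units,n_trials session size.
#' @param type_proportions named 5-vector over types I–V, summing to 1.
#' @param behavioral_accuracy fraction of trials with the correct outcome,
#'   in (0, 1].
#' @param odorless_fraction fraction of trials with no odor presented
#'   (control trials; the animal stays, no reward).
#' @param baseline_median_hz,baseline_iqr_hz median and `c(q1, q3)` of the
#'   baseline-rate distribution.
#' @param sampling_go_ms,sampling_nogo_ms `c(median, q1, q3)` of the
#'   odor-sampling duration (ms) per trial type.
#' @param odor_presentation_s odor valve-open duration; also the lower clip
#'   on sampling durations (the nose poke is enforced during presentation).
#' @param latency_jitter_sd trial-to-trial SD (s) of the cue-response peak
#'   latency.
#' @param min_responsive_baseline_hz near-silent units (baseline below this
#'   rate) are assigned the non-responsive archetype: a response phenotype
#'   is an observable property, and a unit firing a handful of spikes per
#'   session cannot express one.
#' @param excitation_gain,suppression_gain,peak_latency,peak_width,
#'   suppression_onset,suppression_persistence archetype effect parameters
#'   (see [archetype_params()]).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_units = 100L,
                             n_trials = 200L,
                             type_proportions = c(I = 0.389, II = 0.058,
                                                  III = 0.115, IV = 0.170,
                                                  V = 0.268),
                             behavioral_accuracy = 0.9,
                             odorless_fraction = 0,
                             baseline_median_hz = 0.90,
                             baseline_iqr_hz = c(0.23, 3.07),
                             sampling_go_ms = c(788, 669, 962),
                             sampling_nogo_ms = c(642, 562, 798),
                             odor_presentation_s = 0.5,
                             latency_jitter_sd = 0.020,
                             min_responsive_baseline_hz = 0.2,
                             excitation_gain = 5,
                             suppression_gain = 0.2,
                             peak_latency = 0.5,
                             peak_width = 0.08,
                             suppression_onset = 0.3,
                             suppression_persistence = 0.8) {
  stopifnot(n_units >= 1, n_trials >= 2,
            length(type_proportions) == 5,
            all(type_proportions >= 0),
            abs(sum(type_proportions) - 1) < 1e-8)
  if (!(behavioral_accuracy > 0 && behavioral_accuracy <= 1)) {
    stop("behavioral_accuracy must lie in (0, 1]", call. = FALSE)
  }
  cfg <- as.list(environment())
  names(cfg$type_proportions) <- c("I", "II", "III", "IV", "V")
  class(cfg) <- "generator_config"
  cfg
}

# log-normal (meanlog, sdlog) matched to a printed median and IQR:
# meanlog = ln(median); sdlog = ln(q3/q1) / (2 * qnorm(0.75))
lognormal_from_quantiles <- function(median, q1, q3) {
  c(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Sample baseline firing rates
#'
#' I.i.d. log-normal draws whose parameters are solved from the configured
#' median and interquartile range.
#'
#' @param n number of draws (>= 1).
#' @param config a [generator_config()].
#' @param seed optional integer seed.
#' @return numeric vector of rates (Hz).
#' @export
sample_baseline_rates <- function(n, config = generator_config(), seed = NULL) {
  if (!(is.numeric(n) && length(n) == 1L && n >= 1)) {
    stop("n must be a positive count", call. = FALSE)
  }
  p <- lognormal_from_quantiles(config$baseline_median_hz,
                                config$baseline_iqr_hz[1],
                                config$baseline_iqr_hz[2])
  with_seed(seed, stats::rlnorm(n, p["meanlog"], p["sdlog"]))
}

sample_sampling_durations <- function(n, trial_type, config) {
  q <- if (trial_type == "go") config$sampling_go_ms else config$sampling_nogo_ms
  p <- lognormal_from_quantiles(q[1] / 1000, q[2] / 1000, q[3] / 1000)
  pmax(stats::rlnorm(n, p["meanlog"], p["sdlog"]), config$odor_presentation_s)
}

#' Simulate the behavioral trial table
#'
#' Randomized, balanced go/no-go trials; errors occur with probability
#' `1 - behavioral_accuracy`; odor-sampling durations follow the configured
#' clipped log-normals; inter-trial gaps are long enough that analysis epochs
#' of distinct trials never overlap.
#'
#' @inheritParams sample_baseline_rates
#' @return data.frame with the session trial columns.
#' @export
make_trial_table <- function(config = generator_config(), seed = NULL) {
  n <- config$n_trials
  stopifnot(n >= 2)
  with_seed(seed, {
    n_go <- floor(n / 2)
    ttype <- sample(rep(c("go", "no-go"), c(n_go, n - n_go)))
    odor <- ifelse(ttype == "go", "go-cue", "no-go-cue")
    outcome <- ifelse(stats::runif(n) < config$behavioral_accuracy,
                      "correct", "error")
    if (config$odorless_fraction > 0) {
      odorless <- stats::runif(n) < config$odorless_fraction
      # odorless control trials: the animal stays at the port, no reward
      ttype[odorless] <- "no-go"
      outcome[odorless] <- "correct"
      odor[odorless] <- "odorless"
    }
    dur <- numeric(n)
    for (tt in c("go", "no-go")) {
      idx <- ttype == tt
      dur[idx] <- sample_sampling_durations(sum(idx), tt, config)
    }
    iti_end <- odor_on <- port_exit <- numeric(n)
    water_entry <- water_on <- rep(NA_real_, n)
    cursor <- 2.0
    for (i in seq_len(n)) {
      iti_end[i] <- cursor + stats::runif(1, 1.2, 2.0)
      odor_on[i] <- iti_end[i] + stats::runif(1, 0.3, 0.7)
      port_exit[i] <- odor_on[i] + dur[i]
      go_executed <- (ttype[i] == "go") == (outcome[i] == "correct")
      if (odor[i] == "odorless") go_executed <- FALSE
      if (go_executed) {
        water_entry[i] <- port_exit[i] + stats::runif(1, 0.25, 0.5)
        if (ttype[i] == "go" && outcome[i] == "correct") {
          water_on[i] <- water_entry[i] + 0.15
        }
      }
      cursor <- max(port_exit[i] + config$suppression_persistence,
                    port_exit[i] + 1.0, water_entry[i] + 1.0,
                    water_on[i] + 1.0, na.rm = TRUE) + 0.3
    }
    data.frame(trial_id = seq_len(n), trial_type = ttype, outcome = outcome,
               odor_kind = odor, iti_end_s = iti_end, odor_on_s = odor_on,
               odor_off_s = odor_on + config$odor_presentation_s,
               port_exit_s = port_exit, water_entry_s = water_entry,
               water_on_s = water_on)
  })
}

#' Archetype parameters for one unit
#'
#' The five response archetypes:
#' \describe{
#'   \item{I}{go-cue responsive: sharp excitatory peak during go-cue
#'     sampling, persistent suppression through the latter no-go-cue
#'     sampling epoch (sustained past port exit), drinking excitation and
#'     waiting suppression.}
#'   \item{II}{no-go-cue responsive: the mirror image of type I.}
#'   \item{III}{cue excitatory: the excitation peak on both odors, no
#'     preference.}
#'   \item{IV}{cue suppressed: the suppression on both odors, no
#'     preference.}
#'   \item{V}{cue non-responsive: constant baseline.}
#' }
#'
#' @param type_label one of `"I".."V"`.
#' @param baseline_rate baseline firing rate (Hz), > 0.
#' @param config a [generator_config()] supplying the effect sizes.
#' @return An `archetype_params` list.
#' @export
archetype_params <- function(type_label, baseline_rate,
                             config = generator_config()) {
  stopifnot(type_label %in% c("I", "II", "III", "IV", "V"),
            baseline_rate > 0)
  # excitation profile: "phasic" = Gaussian bump at peak_latency (the
  # sharp cue peak of types I/II); "sustained" = epoch-wide rate gain
  # (types III/IV respond to both cues without preference, so their
  # response is tied to the sampling epoch itself, keeping the mean epoch
  # rate identical across cue odors despite different sampling durations)
  gains <- switch(type_label,
    I   = list(go_exc = "phasic", go_sup = FALSE, nogo_exc = "none",
               nogo_sup = TRUE, sup_onset = config$suppression_onset,
               sup_persist = config$suppression_persistence,
               drinking_gain = 3.0, waiting_gain = 0.4),
    II  = list(go_exc = "none", go_sup = TRUE, nogo_exc = "phasic",
               nogo_sup = FALSE, sup_onset = config$suppression_onset,
               sup_persist = config$suppression_persistence,
               drinking_gain = 0.4, waiting_gain = 2.5),
    III = list(go_exc = "sustained", go_sup = FALSE,
               nogo_exc = "sustained", nogo_sup = FALSE,
               sup_onset = 0, sup_persist = 0,
               drinking_gain = 1.0, waiting_gain = 1.0),
    IV  = list(go_exc = "none", go_sup = TRUE, nogo_exc = "none",
               nogo_sup = TRUE, sup_onset = 0, sup_persist = 0,
               drinking_gain = 1.0, waiting_gain = 2.0),
    V   = list(go_exc = "none", go_sup = FALSE, nogo_exc = "none",
               nogo_sup = FALSE, sup_onset = 0, sup_persist = 0,
               drinking_gain = 1.0, waiting_gain = 1.0))
  structure(c(list(type_label = type_label, baseline_rate = baseline_rate,
                   excitation_gain = config$excitation_gain,
                   suppression_gain = config$suppression_gain,
                   peak_latency = config$peak_latency,
                   peak_width = config$peak_width,
                   suppression_onset = gains$sup_onset,
                   suppression_persistence = gains$sup_persist),
              gains),
            class = "archetype_params")
}

# Gaussian bump amplitude such that the integral of lambda over the bump
# window (peak +/- 3 SD) is excitation_gain times the baseline integral.
bump_amplitude <- function(params) {
  (params$excitation_gain - 1) * params$baseline_rate * 6 / sqrt(2 * pi)
}

#' Trial intensity function for an archetype
#'
#' Returns the non-negative firing-rate function \eqn{\lambda(t)} (Hz,
#' session clock) an archetype follows on one trial. Error and odorless
#' trials fire at baseline. The excitatory response is a Gaussian bump
#' peaking `peak_latency` (+ `jitter`) after odor onset; the suppressed
#' response multiplies the baseline by `suppression_gain` from
#' `odor_on + suppression_onset` until
#' `port_exit + suppression_persistence`; drinking and waiting multipliers
#' apply over 1 s epochs anchored at water onset and port exit.
#'
#' @param params an [archetype_params()].
#' @param trial one-row trial table.
#' @param jitter trial-specific latency jitter (s).
#' @return list with `fun` (vectorized over `t`) and `lambda_max`, an upper
#'   bound on `fun` for thinning.
#' @export
intensity_function <- function(params, trial, jitter = 0) {
  b <- params$baseline_rate
  modulated <- trial$outcome == "correct" && trial$odor_kind != "odorless"
  if (!modulated || params$type_label == "V") {
    return(list(fun = function(t) rep(b, length(t)), lambda_max = b))
  }
  is_go <- trial$trial_type == "go"
  exc <- if (is_go) params$go_exc else params$nogo_exc
  sup <- if (is_go) params$go_sup else params$nogo_sup
  amp <- if (identical(exc, "phasic")) bump_amplitude(params) else 0
  sus_win <- if (identical(exc, "sustained")) {
    c(trial$odor_on_s, trial$port_exit_s)
  } else NULL
  t_peak <- trial$odor_on_s + params$peak_latency + jitter
  sup_win <- c(trial$odor_on_s + params$suppression_onset,
               trial$port_exit_s + params$suppression_persistence)
  drink_win <- if (!is.na(trial$water_on_s)) {
    c(trial$water_on_s, trial$water_on_s + 1.0)
  } else NULL
  wait_win <- if (!is_go) c(trial$port_exit_s, trial$port_exit_s + 1.0) else NULL
  dg <- params$drinking_gain
  wg <- params$waiting_gain
  fun <- function(t) {
    mult <- rep(1, length(t))
    if (sup) {
      mult[t >= sup_win[1] & t < sup_win[2]] <-
        mult[t >= sup_win[1] & t < sup_win[2]] * params$suppression_gain
    }
    if (!is.null(sus_win)) {
      idx <- t >= sus_win[1] & t < sus_win[2]
      mult[idx] <- mult[idx] * params$excitation_gain
    }
    if (!is.null(drink_win)) {
      idx <- t >= drink_win[1] & t < drink_win[2]
      mult[idx] <- mult[idx] * dg
    }
    if (!is.null(wait_win)) {
      idx <- t >= wait_win[1] & t < wait_win[2]
      mult[idx] <- mult[idx] * wg
    }
    pmax(b * mult + amp * exp(-(t - t_peak)^2 / (2 * params$peak_width^2)), 0)
  }
  list(fun = fun,
       lambda_max = b * max(1, dg, wg) *
         max(1, if (is.null(sus_win)) 1 else params$excitation_gain) +
         amp + 1e-9)
}

#' Inhomogeneous-Poisson spike times by thinning
#'
#' Candidate events from a homogeneous Poisson process at `lambda_max` are
#' retained with probability `lambda_fun(t) / lambda_max`.
#'
#' @param lambda_fun vectorized rate function (Hz).
#' @param lambda_max upper bound on `lambda_fun` over `[t0, t1)`.
#' @param t0,t1 interval bounds (s).
#' @return sorted spike times.
#' @export
sim_inhomogeneous <- function(lambda_fun, lambda_max, t0, t1) {
  stopifnot(t1 >= t0, lambda_max >= 0)
  n_cand <- stats::rpois(1, lambda_max * (t1 - t0))
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, t0, t1))
  keep <- stats::runif(n_cand) * lambda_max < lambda_fun(cand)
  cand[keep]
}

# Interval of a trial during which the archetype intensity can differ from
# baseline (used to patch the baseline process by local thinning).
modulation_window <- function(trial, config) {
  c(trial$odor_on_s - 0.05,
    max(trial$port_exit_s + config$suppression_persistence,
        trial$port_exit_s + 1.0, trial$water_on_s + 1.0, na.rm = TRUE))
}

#' Generate a full synthetic session with ground truth
#'
#' Unit archetypes are drawn from the configured type proportions, baseline
#' rates from the log-normal baseline distribution, behavior from
#' [make_trial_table()], and spikes from each unit's inhomogeneous Poisson
#' intensity by thinning. Deterministic given `seed`.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param session_id identifier stored in the session.
#' @return list with elements `session` (a [gng_session()]) and
#'   `ground_truth` (data.frame: `unit_id`, `type_label`, `baseline_hz`),
#'   with per-unit parameter lists in `attr(ground_truth, "params")`.
#' @export
generate_session <- function(config = generator_config(), seed = 1L,
                             session_id = sprintf("synthetic-%06d", seed)) {
  trials <- make_trial_table(config, seed = child_seed(seed, 1L))
  baselines <- sample_baseline_rates(config$n_units, config,
                                     seed = child_seed(seed, 3L))
  types <- with_seed(child_seed(seed, 2L), {
    lab <- sample(names(config$type_proportions), config$n_units,
                  replace = TRUE, prob = config$type_proportions)
    # a response phenotype is observable only in units with measurable
    # baseline activity: non-responsive labels are assigned to near-silent
    # units first, the remaining labels are shuffled over the rest
    out <- character(config$n_units)
    low <- which(baselines < config$min_responsive_baseline_hz)
    n_v <- sum(lab == "V")
    v_first <- low[seq_len(min(n_v, length(low)))]
    out[v_first] <- "V"
    rest_labels <- c(rep("V", n_v - length(v_first)), lab[lab != "V"])
    rest_idx <- setdiff(seq_len(config$n_units), v_first)
    out[rest_idx] <- sample(rest_labels)
    out
  })
  n_tr <- nrow(trials)
  t_end <- max(trials$port_exit_s, trials$water_on_s + 1.5,
               trials$water_entry_s + 1.5, na.rm = TRUE) + 2.0
  mod_win <- t(vapply(seq_len(n_tr),
                      function(i) modulation_window(trials[i, ], config),
                      numeric(2)))
  units <- vector("list", config$n_units)
  params_list <- vector("list", config$n_units)
  for (u in seq_len(config$n_units)) {
    params <- archetype_params(types[u], baselines[u], config)
    params_list[[u]] <- params
    units[[u]] <- with_seed(child_seed(seed, 100L + u), {
      b <- baselines[u]
      # baseline process over the whole session, excised inside windows
      # where the intensity is modulated, then regenerated there by thinning
      base <- sort(stats::runif(stats::rpois(1, b * t_end), 0, t_end))
      if (types[u] != "V") {
        # modulation windows are disjoint and sorted; odd interval index
        # from the flattened bounds means "inside a window"
        in_mod <- findInterval(base, as.vector(t(mod_win))) %% 2L == 1L
        base <- base[!in_mod]
        jit <- stats::rnorm(n_tr, 0, config$latency_jitter_sd)
        extra <- lapply(seq_len(n_tr), function(i) {
          lam <- intensity_function(params, trials[i, ], jitter = jit[i])
          sim_inhomogeneous(lam$fun, lam$lambda_max,
                            mod_win[i, 1], mod_win[i, 2])
        })
        base <- sort(c(base, unlist(extra)))
      }
      spike_train(sprintf("u%03d", u), base)
    })
  }
  gt <- data.frame(unit_id = sprintf("u%03d", seq_len(config$n_units)),
                   type_label = types, baseline_hz = baselines,
                   stringsAsFactors = FALSE)
  attr(gt, "params") <- params_list
  attr(gt, "seed") <- seed
  meta <- list(subject_id = "synthetic", generator_seed = seed,
               behavioral_accuracy = config$behavioral_accuracy,
               odor_presentation_s = config$odor_presentation_s)
  list(session = gng_session(session_id, units, trials, meta = meta),
       ground_truth = gt)
}

#' Write ground truth beside a session directory
#' @param ground_truth data.frame from [generate_session()].
#' @param path session directory.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.csv(ground_truth, file.path(path, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
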