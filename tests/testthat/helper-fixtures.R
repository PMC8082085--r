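# Shared fixtures, built in code.

# Minimal hand-written trial table: events strictly ordered, one trial of
# each kind.
tiny_trials <- function() {
  data.frame(
    trial_id = 1:4,
    trial_type = c("go", "no-go", "go", "no-go"),
    outcome = c("correct", "correct", "error", "error"),
    odor_kind = c("go-cue", "no-go-cue", "go-cue", "no-go-cue"),
    iti_end_s = c(10, 20, 30, 40),
    odor_on_s = c(10.5, 20.5, 30.5, 40.5),
    odor_off_s = c(11, 21, 31, 41),
    port_exit_s = c(11.3, 21.14, 31.3, 41.14),
    water_entry_s = c(11.7, NA, NA, 41.6),
    water_on_s = c(11.9, NA, NA, NA))
}

tiny_session <- function() {
  gng_session(
    "tiny",
    list(spike_train("a", c(0.5, 10.2, 10.9, 11.1, 21.0)),
         spike_train("b", c(5, 15, 25, 35, 45))),
    tiny_trials(),
    meta = list(subject_id = "m1"))
}

# One default-conditions synthetic session, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_default_session <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_session(generator_config(),
                                              seed = seed)
  }
  .fixture_cache[[key]]
}

# Regenerate a session's single unit as an archetype with a pinned
# baseline rate (power control in planted-effect tests).
regen_unit <- function(session, type, baseline, cfg, seed) {
  params <- archetype_params(type, baseline, cfg)
  trials <- session$trials
  spikes <- with_seed(seed + 1, {
    unlist(lapply(seq_len(nrow(trials)), function(i) {
      lam <- intensity_function(params, trials[i, ])
      sim_inhomogeneous(lam$fun, lam$lambda_max,
                        trials$iti_end_s[i] - 1.2,
                        trials$port_exit_s[i] + 2.0)
    }))
  })
  spike_train(session$units[[1]]$unit_id, sort(spikes))
}

# Single-archetype session with a pinned baseline rate.
archetype_session <- function(type, baseline = 4, n_trials = 140, seed = 17,
                              ...) {
  cfg <- generator_config(n_units = 1L, n_trials = n_trials,
                          type_proportions =
                            setNames(as.numeric(c("I", "II", "III", "IV",
                                                  "V") == type),
                                     c("I", "II", "III", "IV", "V")),
                          ...)
  gen <- generate_session(cfg, seed = seed)
  gen$session$units[[1]] <- regen_unit(gen$session, type, baseline, cfg,
                                       seed)
  gen$session
}

# Unit with a planted rectangular response window relative to odor onset
# on correct trials of one type: kind "excitation" adds `amp` Hz inside
# the window, "suppression" silences the baseline inside it.
planted_unit <- function(session, win, kind = "excitation", baseline = 4,
                         amp = 20, trial_type = "go", seed = 1) {
  trials <- session$trials
  on_trial <- trials$trial_type == trial_type & trials$outcome == "correct"
  spikes <- with_seed(seed, {
    t_end <- max(trials$port_exit_s, trials$water_on_s, na.rm = TRUE) + 2
    lam_max <- baseline + if (kind == "excitation") amp else 0
    lam <- function(t) {
      out <- rep(baseline, length(t))
      i <- findInterval(t, trials$odor_on_s)
      active <- i >= 1 & on_trial[pmax(i, 1L)]
      rel <- t - trials$odor_on_s[pmax(i, 1L)]
      inside <- active & rel >= win[1] & rel < win[2]
      if (kind == "excitation") out[inside] <- out[inside] + amp
      else out[inside] <- 0
      out
    }
    sim_inhomogeneous(lam, lam_max, 0, t_end)
  })
  spike_train("planted", spikes)
}

# Brute-force auROC by exhaustive pair counting — independent oracle.
auroc_bruteforce <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(a) * length(b))
}
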