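# Five-type classification of units from their odor-sampling epoch response.

#' Classification configuration
#'
#' @param alpha significance level for every permutation test (0.01).
#' @param n_perm permutation count per test.
#' @param min_trials minimum correct trials per condition for a unit to be
#'   classifiable.
#' @export
classify_config <- function(alpha = 0.01, n_perm = 1000L, min_trials = 10L) {
  list(alpha = alpha, n_perm = n_perm, min_trials = min_trials)
}

#' Classify one unit into response types I–V
#'
#' Statistics are computed on correct trials, comparing per-trial firing
#' rates in the odor-sampling epoch against the long baseline (1000–0 ms
#' before ITI end). Decision rules:
#' \enumerate{
#'   \item no significant response to either cue odor → type V
#'     (cue non-responsive);
#'   \item significant go-vs-no-go preference: auROC > 0.5 → type I
#'     (go-cue responsive), < 0.5 → type II (no-go-cue responsive);
#'   \item no preference and every significant cue response excitatory →
#'     type III; every one suppressed → type IV;
#'   \item mixed directions without preference: the direction of the larger
#'     `|auROC - 0.5|` across the two cues decides III vs IV; an exact tie
#'     falls back to type V.
#' }
#'
#' @param unit a [spike_train()].
#' @param session a [gng_session()].
#' @param config a [classify_config()].
#' @param seed optional seed (fanned out across the three tests).
#' @return A `neuron_classification` list: `unit_id`, `type_label` (NA if
#'   unclassifiable), `classifiable`, and the three `auroc_result`s
#'   (`go`, `nogo`, `preference`).
#' @export
classify_neuron <- function(unit, session, config = classify_config(),
                            seed = NULL) {
  go <- trial_category(session$trials, "correct_go")
  nogo <- trial_category(session$trials, "correct_no_go")
  if (nrow(go) < config$min_trials || nrow(nogo) < config$min_trials) {
    return(structure(list(unit_id = unit$unit_id, type_label = NA_character_,
                          classifiable = FALSE, go = NULL, nogo = NULL,
                          preference = NULL),
                     class = "neuron_classification"))
  }
  rate_go <- epoch_rates(unit, go, "odor_sampling")
  rate_nogo <- epoch_rates(unit, nogo, "odor_sampling")
  base_go <- epoch_rates(unit, go, "baseline_long")
  base_nogo <- epoch_rates(unit, nogo, "baseline_long")
  s <- function(i) if (is.null(seed)) NULL else child_seed(seed, i)
  res_go <- auroc_test(rate_go, base_go, n_perm = config$n_perm,
                       seed = s(1L), alpha = config$alpha)
  res_nogo <- auroc_test(rate_nogo, base_nogo, n_perm = config$n_perm,
                         seed = s(2L), alpha = config$alpha)
  res_pref <- auroc_test(rate_go, rate_nogo, n_perm = config$n_perm,
                         seed = s(3L), alpha = config$alpha)
  sig_go <- res_go$direction != "none"
  sig_nogo <- res_nogo$direction != "none"
  type <- if (!sig_go && !sig_nogo) {
    "V"
  } else if (res_pref$direction == "excitation") {
    "I"
  } else if (res_pref$direction == "suppression") {
    "II"
  } else {
    dirs <- c(if (sig_go) res_go$direction, if (sig_nogo) res_nogo$direction)
    if (all(dirs == "excitation")) "III"
    else if (all(dirs == "suppression")) "IV"
    else {
      # mixed directions without preference: larger |auROC - 0.5| decides
      dev_go <- abs(res_go$auroc - 0.5)
      dev_nogo <- abs(res_nogo$auroc - 0.5)
      if (dev_go == dev_nogo) "V"
      else if ((if (dev_go > dev_nogo) res_go else res_nogo)$direction ==
               "excitation") "III" else "IV"
    }
  }
  structure(list(unit_id = unit$unit_id, type_label = type,
                 classifiable = TRUE, go = res_go, nogo = res_nogo,
                 preference = res_pref),
            class = "neuron_classification")
}

#' Classify every unit in a session
#'
#' @inheritParams classify_neuron
#' @return data.frame with one row per unit: `unit_id`, `type_label`,
#'   `classifiable`, auROC/p/direction for the go and no-go cue responses
#'   and the go-vs-no-go preference.
#' @export
classify_session <- function(session, config = classify_config(),
                             seed = NULL) {
  rows <- lapply(seq_along(session$units), function(u) {
    cl <- classify_neuron(session$units[[u]], session, config,
                          seed = if (is.null(seed)) NULL
                                 else child_seed(seed, u))
    pull <- function(res, field) if (is.null(res)) NA else res[[field]]
    data.frame(unit_id = cl$unit_id, type_label = cl$type_label,
               classifiable = cl$classifiable,
               auroc_go = pull(cl$go, "auroc"),
               p_go = pull(cl$go, "p_value"),
               dir_go = pull(cl$go, "direction"),
               auroc_nogo = pull(cl$nogo, "auroc"),
               p_nogo = pull(cl$nogo, "p_value"),
               dir_nogo = pull(cl$nogo, "direction"),
               auroc_pref = pull(cl$preference, "auroc"),
               p_pref = pull(cl$preference, "p_value"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summary proportions from a classification table
#'
#' @param classifications output of [classify_session()].
#' @return list: `type_proportions` (over classifiable units),
#'   `pct_responsive` (significant response to at least one cue),
#'   `pct_go_preferring` and `pct_nogo_preferring` (fractions of all
#'   classified units with a significant preference), all in percent.
#' @export
classification_summary <- function(classifications) {
  cl <- classifications[classifications$classifiable, , drop = FALSE]
  if (!nrow(cl)) stop("no classifiable units", call. = FALSE)
  props <- table(factor(cl$type_label, levels = c("I", "II", "III", "IV", "V")))
  list(type_proportions = as.numeric(props) / nrow(cl),
       n_classified = nrow(cl),
       pct_responsive = 100 * mean(cl$type_label != "V"),
       pct_go_preferring = 100 * mean(cl$type_label == "I"),
       pct_nogo_preferring = 100 * mean(cl$type_label == "II"))
}
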