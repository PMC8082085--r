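# End-to-end orchestration: synthesize-or-load a session, classify,
# compute traces, encoding model, population geometry and decoding, and
# write tabular/JSON outputs with a reproducibility manifest.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a session) or `"session_dir"`
#'   (load one from `session_dir`).
#' @param generator a [generator_config()] (synthetic mode).
#' @param session_dir directory with a written session (session_dir mode).
#' @param seed global seed, fanned out per stage via [child_seed()].
#' @param n_perm permutation count for classification and traces.
#' @param alpha significance level.
#' @param trace_window sliding-trace window around odor onset.
#' @param glm_max_units at most this many go-cue responsive units go
#'   through the encoding model.
#' @param decoding_sizes,decoding_centers,decoding_resamples decoding
#'   stage parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "session_dir"),
                            generator = generator_config(),
                            session_dir = NULL,
                            seed = 1L,
                            n_perm = 1000L, alpha = 0.01,
                            trace_window = c(-0.1, 1.0),
                            glm_max_units = 10L,
                            decoding_sizes = c(5L, 25L, 100L),
                            decoding_centers = c(0.05, 0.2, 0.45, 0.6),
                            decoding_resamples = 5L) {
  mode <- match.arg(mode)
  if (mode == "session_dir" && (is.null(session_dir) ||
                                !dir.exists(session_dir))) {
    stop("session_dir mode requires an existing session directory",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

write_stage_csv <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                   quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: session (generate or load), classification, sliding auROC
#' traces for the go-cue responsive units, encoding model, population
#' geometry, decoding. Each stage's tables are written under `out_dir`;
#' `manifest.json` records the config hash, seeds, package version and
#' per-stage wall times. Any stage error aborts the run (fail-fast) with
#' the stage name in the message.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("gonogo")),
                   seed = config$seed, stages = list())
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      seed = child_seed(config$seed, match(stage, PIPELINE_STAGES)))
    res
  }
  seed_of <- function(stage) child_seed(config$seed,
                                        match(stage, PIPELINE_STAGES))

  ground_truth <- NULL
  session <- timed("session", {
    if (config$mode == "synthetic") {
      gen <- generate_session(config$generator, seed = seed_of("session"))
      ground_truth <- gen$ground_truth
      sess_dir <- file.path(out_dir, "session")
      write_session(gen$session, sess_dir)
      write_ground_truth(gen$ground_truth, sess_dir)
      gen$session
    } else {
      s <- load_session(config$session_dir)
      gt_file <- file.path(config$session_dir, "ground_truth.csv")
      if (file.exists(gt_file)) {
        ground_truth <- utils::read.csv(gt_file,
                                        stringsAsFactors = FALSE,
                                        colClasses =
                                          c(unit_id = "character"))
      }
      s
    }
  })

  cls <- timed("classify", {
    cc <- classify_config(alpha = config$alpha, n_perm = config$n_perm)
    out <- classify_session(session, cc, seed = seed_of("classify"))
    write_stage_csv(out, out_dir, "classifications.csv")
    out
  })

  traces <- timed("traces", {
    type1 <- cls$unit_id[cls$classifiable & cls$type_label == "I"]
    rows <- list()
    meas <- list()
    for (i in seq_along(type1)) {
      for (cond in c("go_vs_baseline", "nogo_vs_baseline")) {
        tr <- sliding_auroc(session$units[[type1[i]]], session, cond,
                            window = config$trace_window,
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = child_seed(seed_of("traces"),
                                              2L * i + (cond ==
                                                        "go_vs_baseline")))
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = type1[i], condition = cond,
          bin_center_s = tr$bin_center, auroc = tr$auroc,
          significant = tr$significant, direction = tr$direction)
        meas[[length(meas) + 1L]] <- data.frame(
          unit_id = type1[i], condition = cond,
          onset_time = attr(tr, "onset_time"),
          center_of_mass = attr(tr, "center_of_mass"),
          duration = attr(tr, "duration"))
      }
    }
    if (length(rows)) {
      write_stage_csv(do.call(rbind, rows), out_dir, "traces.csv")
      write_stage_csv(do.call(rbind, meas), out_dir, "trace_measures.csv")
    }
    if (length(meas)) do.call(rbind, meas) else NULL
  })

  timed("glm", {
    type1 <- cls$unit_id[cls$classifiable & cls$type_label == "I"]
    type1 <- utils::head(type1, config$glm_max_units)
    if (length(type1)) {
      fits <- encode_units(session$units[type1], session,
                           seed = seed_of("glm"))
      write_stage_csv(fits, out_dir, "glm_fits.csv")
    }
    NULL
  })

  timed("geometry", {
    pm <- build_population_matrix(session)
    sub <- pca_subspace(pm, k = min(3L, dim(pm)[1]))
    dist <- trajectory_distance(pm)
    vel <- trajectory_velocity(pm, condition = 1L)
    traj <- data.frame(
      condition = rep(attr(pm, "conditions"),
                      each = length(sub$bin_centers)),
      bin_center_s = rep(sub$bin_centers, dim(pm)[3]))
    for (d in seq_len(nrow(sub$trajectories))) {
      traj[[paste0("pc", d)]] <- as.numeric(sub$trajectories[d, , ])
    }
    write_stage_csv(traj, out_dir, "trajectories.csv")
    geom <- rbind(
      data.frame(kind = "distance", bin_center_s = dist$bin_center,
                 value = dist$value, significant = dist$significant),
      data.frame(kind = "velocity", bin_center_s = vel$bin_center,
                 value = vel$value, significant = vel$significant))
    write_stage_csv(geom, out_dir, "geometry.csv")
    w <- neural_weights(sub)
    types <- cls$type_label[match(sub$unit_ids,
                                  paste0(session$session_id, "/",
                                         cls$unit_id))]
    write_stage_csv(data.frame(unit_id = sub$unit_ids, type_label = types,
                               weight = unname(w)),
                    out_dir, "weights.csv")
    NULL
  })

  timed("decoding", {
    dc <- decoding_timecourse(session,
                              population_sizes = config$decoding_sizes,
                              centers = config$decoding_centers,
                              n_resamples = config$decoding_resamples,
                              seed = seed_of("decoding"))
    write_stage_csv(as.data.frame(dc), out_dir, "decoding.csv")
    jsonlite::write_json(
      list(behavioral_accuracy = attr(dc, "behavioral_accuracy"),
           chance = attr(dc, "chance"),
           min_units_reaching_behavior =
             as.list(attr(dc, "min_units_reaching_behavior"))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    NULL
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

PIPELINE_STAGES <- c("session", "classify", "traces", "glm", "geometry",
                     "decoding")

#' Summarize a completed pipeline run
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return list: per-type proportions, percent responsive, mean GLM
#'   contributions, decoding minimum-units table, and — when ground truth
#'   is available — the confusion matrix and recovery rate of the
#'   classification. Printed as a human-readable summary.
#' @export
report_summary <- function(out_dir) {
  needed <- c("classifications.csv", "geometry.csv", "decoding.csv",
              "summary.json", "manifest.json")
  missing <- needed[!file.exists(file.path(out_dir, needed))]
  if (length(missing)) {
    stop("incomplete run; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cls <- utils::read.csv(file.path(out_dir, "classifications.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(unit_id = "character"))
  summ <- classification_summary(cls)
  out <- list(type_proportions = summ$type_proportions,
              pct_responsive = summ$pct_responsive,
              n_classified = summ$n_classified)
  glm_file <- file.path(out_dir, "glm_fits.csv")
  if (file.exists(glm_file)) {
    fits <- utils::read.csv(glm_file)
    out$glm_mean_contrib <- c(
      odor_onset = mean(fits$contrib_odor_onset),
      pre_port_exit = mean(fits$contrib_pre_exit))
  }
  dec <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                             simplifyVector = TRUE)
  out$min_units_reaching_behavior <- dec$min_units_reaching_behavior
  out$behavioral_accuracy <- dec$behavioral_accuracy
  gt_file <- file.path(out_dir, "session", "ground_truth.csv")
  if (file.exists(gt_file)) {
    gt <- utils::read.csv(gt_file, stringsAsFactors = FALSE,
                          colClasses = c(unit_id = "character"))
    m <- merge(cls[cls$classifiable, c("unit_id", "type_label")],
               gt[, c("unit_id", "type_label")], by = "unit_id",
               suffixes = c("_called", "_true"))
    out$confusion <- table(true = m$type_label_true,
                           called = m$type_label_called)
    out$recovery_rate <- mean(m$type_label_called == m$type_label_true)
  }
  cat("Units classified:", out$n_classified, "\n")
  cat(sprintf("Type proportions (I-V): %s\n",
              paste(sprintf("%.1f%%", 100 * out$type_proportions),
                    collapse = " / ")))
  cat(sprintf("Cue-responsive: %.1f%%\n", out$pct_responsive))
  if (!is.null(out$glm_mean_contrib)) {
    cat(sprintf("GLM mean contributions: odor-onset %.1f%%, pre-exit %.1f%%\n",
                100 * out$glm_mean_contrib[["odor_onset"]],
                100 * out$glm_mean_contrib[["pre_port_exit"]]))
  }
  if (!is.null(out$recovery_rate)) {
    cat(sprintf("Ground-truth recovery: %.1f%%\n", 100 * out$recovery_rate))
  }
  invisible(out)
}
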