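test_that("baseline-rate distribution reproduces the target quantiles", {
  r <- sample_baseline_rates(10000, seed = 11)
  q <- quantile(r, c(0.25, 0.5, 0.75))
  expect_lt(abs(q[[2]] - 0.90) / 0.90, 0.10)
  expect_lt(abs(q[[1]] - 0.23) / 0.23, 0.15)
  expect_lt(abs(q[[3]] - 3.07) / 3.07, 0.15)
  expect_identical(sample_baseline_rates(50, seed = 3),
                   sample_baseline_rates(50, seed = 3))
  expect_error(sample_baseline_rates(0), "positive")
})

test_that("odor-sampling durations match the task statistics at large n", {
  cfg <- generator_config(n_trials = 20000L)
  tr <- make_trial_table(cfg, seed = 5)
  dur <- tr$port_exit_s - tr$odor_on_s
  med_go <- median(dur[tr$trial_type == "go"])
  med_ng <- median(dur[tr$trial_type == "no-go"])
  expect_lt(abs(med_go - 0.788) / 0.788, 0.03)
  expect_lt(abs(med_ng - 0.642) / 0.642, 0.03)
  expect_true(all(dur >= cfg$odor_presentation_s))
  # >80% behavioral accuracy at the default error rate
  expect_gt(mean(tr$outcome == "correct"), 0.8)
})

test_that("trial tables respect outcome contracts and never overlap", {
  perfect <- make_trial_table(generator_config(n_trials = 200L,
                                               behavioral_accuracy = 1),
                              seed = 2)
  expect_true(all(perfect$outcome == "correct"))
  expect_error(generator_config(behavioral_accuracy = 0), "accuracy")
  tr <- make_trial_table(generator_config(n_trials = 300L), seed = 8)
  # go behavior executed iff (go & correct) or (no-go & error)
  go_exec <- (tr$trial_type == "go") == (tr$outcome == "correct")
  expect_identical(!is.na(tr$water_entry_s), go_exec)
  # analysis epochs of consecutive trials never overlap
  ends <- pmax(tr$port_exit_s + 1.0, tr$water_on_s + 1.0, na.rm = TRUE)
  expect_true(all(tr$iti_end_s[-1] - 1.0 >= ends[-nrow(tr)]))
})

test_that("archetype intensities follow their stated patterns", {
  cfg <- generator_config()
  tr <- tiny_trials()
  b <- 2.3
  lam_v <- intensity_function(archetype_params("V", b, cfg), tr[1, ])
  tt <- seq(9, 13, by = 0.001)
  expect_equal(lam_v$fun(tt), rep(b, length(tt)))

  p1 <- archetype_params("I", b, cfg)
  lam_go <- intensity_function(p1, tr[1, ])
  # quadrature: integral over the bump window (peak +/- 3 SD) exceeds the
  # baseline integral by the excitation gain factor
  t_peak <- tr$odor_on_s[1] + cfg$peak_latency
  win <- seq(t_peak - 3 * cfg$peak_width, t_peak + 3 * cfg$peak_width,
             length.out = 20001)
  integral <- mean(lam_go$fun(win)) * (max(win) - min(win))
  base_integral <- b * (max(win) - min(win))
  expect_equal(integral / base_integral, cfg$excitation_gain,
               tolerance = 0.01)
  expect_true(all(lam_go$fun(tt) >= 0))
  expect_true(all(lam_go$fun(tt) <= lam_go$lambda_max + 1e-9))

  # no-go suppression: with gain 0 the rate is exactly 0 inside the window
  cfg0 <- generator_config(suppression_gain = 0)
  lam_ng <- intensity_function(archetype_params("I", b, cfg0), tr[2, ])
  t_sup <- seq(tr$odor_on_s[2] + cfg0$suppression_onset + 1e-6,
               tr$port_exit_s[2] + cfg0$suppression_persistence - 1e-6,
               by = 0.01)
  expect_equal(lam_ng$fun(t_sup), rep(0, length(t_sup)))
  expect_equal(lam_ng$fun(tr$iti_end_s[2] - 0.5), b)

  # error trials fire at baseline for every archetype
  for (tp in c("I", "II", "III", "IV")) {
    lam_err <- intensity_function(archetype_params(tp, b, cfg), tr[3, ])
    expect_equal(lam_err$fun(tt), rep(b, length(tt)))
  }
})

test_that("thinning reproduces Poisson statistics for constant rates", {
  # type-V-like unit: 1000 s at 2 Hz gives ~2000 spikes
  n <- with_seed(21, length(sim_inhomogeneous(function(t) rep(2, length(t)),
                                              2, 0, 1000)))
  expect_lt(abs(n - 2000), 3 * sqrt(2000))

  # chi-square goodness of fit of counts against Poisson(lambda * T)
  counts <- with_seed(22, replicate(200, {
    length(sim_inhomogeneous(function(t) rep(5, length(t)), 8, 0, 10))
  }))
  mu <- 50
  breaks <- qpois(seq(0, 1, length.out = 9), mu)
  breaks[1] <- -1; breaks[9] <- Inf
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(breaks, mu))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("generated sessions are deterministic and carry ground truth", {
  cfg <- generator_config(n_units = 12L, n_trials = 40L)
  g1 <- generate_session(cfg, seed = 9)
  g2 <- generate_session(cfg, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(g1$session, d1)
  write_session(g2$session, d2)
  for (f in c("units.csv", "trials.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_identical(g1$ground_truth$type_label, g2$ground_truth$type_label)
  expect_equal(nrow(g1$ground_truth), 12L)
  g3 <- generate_session(cfg, seed = 10)
  expect_false(identical(g1$session$units[[1]]$spike_times,
                         g3$session$units[[1]]$spike_times))
})

test_that("archetype proportions follow the configured multinomial", {
  gt <- cached_default_session(1)$ground_truth
  p <- generator_config()$type_proportions
  counts <- table(factor(gt$type_label, levels = names(p)))
  gof <- suppressWarnings(chisq.test(as.numeric(counts), p = p))
  expect_gt(gof$p.value, 0.001)
})
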