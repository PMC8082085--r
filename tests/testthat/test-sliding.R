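make_trace <- function(centers, auroc, significant) {
  data.frame(bin_center = centers, auroc = auroc, significant = significant)
}

test_that("trace measures follow their definitions on hand-made traces", {
  centers <- seq(0.05, 0.65, by = 0.02)
  n <- length(centers)
  none <- make_trace(centers, rep(0.5, n), rep(FALSE, n))
  m0 <- trace_measures(none)
  expect_true(is.na(m0$onset_time))
  expect_equal(m0$duration, 0)

  # an isolated significant bin yields no onset but a one-bin duration
  sig1 <- rep(FALSE, n); sig1[5] <- TRUE
  m1 <- trace_measures(make_trace(centers, rep(0.7, n), sig1))
  expect_true(is.na(m1$onset_time))
  expect_equal(m1$duration, 0.100)
  expect_equal(m1$center_of_mass, centers[5])

  # a run of >= 3 consecutive bins: onset at the left edge of the run,
  # duration the union of overlapping 100 ms spans
  sig2 <- rep(FALSE, n); sig2[6:10] <- TRUE
  m2 <- trace_measures(make_trace(centers, rep(0.8, n), sig2))
  expect_equal(m2$onset_time, centers[6] - 0.05)
  expect_equal(m2$duration, 0.100 + 4 * 0.020)

  # center of mass weights bins by |auROC - 0.5|
  au <- rep(0.5, n); au[6] <- 0.6; au[10] <- 0.9
  sig3 <- rep(FALSE, n); sig3[c(6, 10)] <- TRUE
  m3 <- trace_measures(make_trace(centers, au, sig3))
  expect_equal(m3$center_of_mass,
               (centers[6] * 0.1 + centers[10] * 0.4) / 0.5)
  expect_true(is.na(m3$onset_time))  # isolated bins are not an onset run
})

test_that("planted go-cue excitation is detected at the planted time", {
  # long sampling durations so no bin loses trials to port-exit clipping,
  # keeping the symmetric bump symmetric in the trace
  cfg <- generator_config(n_units = 1L, n_trials = 160L,
                          type_proportions = c(I = 1, II = 0, III = 0,
                                               IV = 0, V = 0),
                          sampling_go_ms = c(1300, 1200, 1400),
                          sampling_nogo_ms = c(1300, 1200, 1400),
                          latency_jitter_sd = 0)
  gen <- generate_session(cfg, seed = 19)
  s <- gen$session
  s$units[[1]] <- regen_unit(s, "I", 6, cfg, 77)
  tr_go <- sliding_auroc(s$units[[1]], s, "go_vs_baseline",
                         n_perm = 500, seed = 4)
  # significant excitation run overlapping 450-550 ms post-onset
  sig_exc <- tr_go$bin_center[tr_go$direction == "excitation"]
  expect_true(any(sig_exc >= 0.45 & sig_exc <= 0.55))
  # symmetric planted bump centered at 500 ms
  expect_lt(abs(attr(tr_go, "center_of_mass") - 0.5), 0.02)
  expect_gt(attr(tr_go, "duration"), 0)
  expect_lte(attr(tr_go, "onset_time"), attr(tr_go, "center_of_mass"))

  # the no-go suppression persists late into the sampling epoch
  tr_ng <- sliding_auroc(s$units[[1]], s, "nogo_vs_baseline",
                         n_perm = 500, seed = 5)
  sup <- tr_ng$bin_center[tr_ng$direction == "suppression"]
  expect_gt(length(sup), 0)
  expect_gt(max(sup), 0.8)
})

test_that("a stationary unit has ~alpha significant bins", {
  gen <- cached_default_session(1)
  s <- gen$session
  gt <- gen$ground_truth[gen$ground_truth$type_label == "V", ]
  v_units <- gt$unit_id[order(-gt$baseline_hz)]
  n_sig <- 0L; n_bins <- 0L
  for (id in head(v_units, 6)) {
    tr <- sliding_auroc(s$units[[id]], s, "go_vs_baseline", n_perm = 300,
                        seed = 13)
    n_sig <- n_sig + sum(tr$significant, na.rm = TRUE)
    n_bins <- n_bins + sum(!is.na(tr$significant))
  }
  expect_lt(n_sig / n_bins, 0.06)
})

test_that("duration comparison matches rank-sum expectations", {
  same <- c(0.2, 0.3, 0.4, 0.5)
  expect_equal(compare_durations(same, same)$p_value, 1)
  set.seed(61)
  exc <- rnorm(30, 0.2, 0.05)
  sup <- rnorm(30, 0.6, 0.15)
  res <- compare_durations(exc, sup)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$median_excitation, res$median_suppression)
  # exhaustive-enumeration oracle on a small fixture without ties
  a <- c(0.11, 0.25, 0.32, 0.47)
  b <- c(0.18, 0.52, 0.61)
  obs_u <- sum(outer(a, b, ">"))
  splits <- combn(7, 4)
  pool <- c(a, b)
  null_u <- apply(splits, 2, function(ix) {
    sum(outer(pool[ix], pool[-ix], ">"))
  })
  mean_u <- 4 * 3 / 2
  p_exact <- mean(abs(null_u - mean_u) >= abs(obs_u - mean_u))
  expect_equal(compare_durations(a, b)$p_value, p_exact, tolerance = 1e-9)
})

test_that("peak and half-width recover a planted Gaussian profile", {
  tr <- tiny_trials()[1, ]
  centers <- seq(-0.49, 0.5, by = 0.02)
  sigma <- 0.08
  rate <- 30 * exp(-(centers - 0.1)^2 / (2 * sigma^2))
  fake <- structure(matrix(rate, nrow = 1), bin_centers = centers,
                    bin_width = 0.02, class = c("smoothed_psth", "matrix"))
  m <- peak_and_halfwidth(fake)
  expect_equal(m$peak_rate, 30, tolerance = 0.01)
  expect_equal(m$half_width, 2.3548 * sigma, tolerance = 0.02)
  expect_lt(abs(m$peak_time - 0.1), 0.011)
  flat <- structure(matrix(5, nrow = 1, ncol = length(centers)),
                    bin_centers = centers, bin_width = 0.02,
                    class = c("smoothed_psth", "matrix"))
  m2 <- peak_and_halfwidth(flat, baseline_rate = 5)
  expect_true(is.na(m2$half_width))
  expect_equal(m2$peak_rate, 5)
})

test_that("odor-locked responses are sharper under odor-onset alignment", {
  cfg <- generator_config(n_units = 24L, n_trials = 120L,
                          type_proportions = c(I = 1, II = 0, III = 0,
                                               IV = 0, V = 0),
                          latency_jitter_sd = 0)
  gen <- generate_session(cfg, seed = 29)
  keep <- gen$ground_truth$baseline_hz > 0.5
  units <- gen$session$units[keep]
  res <- suppressWarnings(alignment_comparison(units, gen$session))
  ok <- complete.cases(res$measures$peak_onset, res$measures$peak_exit)
  frac_higher <- mean(res$measures$peak_onset[ok] >
                        res$measures$peak_exit[ok])
  expect_gte(frac_higher, 0.8)
  expect_lt(res$p_peak, 0.05)
})

test_that("cue response appears only in correct go trials for type I", {
  cfg <- generator_config(n_units = 1L, n_trials = 260L,
                          behavioral_accuracy = 0.8,
                          odorless_fraction = 0.1,
                          type_proportions = c(I = 1, II = 0, III = 0,
                                               IV = 0, V = 0))
  gen <- generate_session(cfg, seed = 31)
  s <- gen$session
  s$units[[1]] <- regen_unit(s, "I", 5, cfg, 31)
  cc <- condition_contrast(s$units[[1]], s, n_perm = 500, seed = 6)
  expect_equal(cc$correct_go$direction, "excitation")
  expect_equal(cc$odorless$direction, "none")
  expect_equal(cc$error$direction, "none")
})

test_that("stability flags follow the planted trial dynamics", {
  cfg <- generator_config(n_units = 1L, n_trials = 80L,
                          type_proportions = c(I = 0, II = 0, III = 0,
                                               IV = 0, V = 1))
  gen <- generate_session(cfg, seed = 37)
  s <- gen$session
  go <- trial_category(s$trials, "correct_go")
  # stationary unit: stable
  u <- regen_unit(s, "V", 4, cfg, 37)
  st <- trial_stability(u, go)
  expect_true(st$stable)
  # planted monotone drift: rate doubles over the session
  drift <- with_seed(41, {
    t_end <- max(s$trials$port_exit_s) + 2
    lam <- function(t) 2 * (1 + t / t_end)
    sim_inhomogeneous(lam, 4.1, 0, t_end)
  })
  st2 <- trial_stability(spike_train("d", drift), go)
  expect_false(st2$stable)
  expect_gt(st2$rho, 0)
  # reversing trial order flips the correlation sign
  st3 <- trial_stability(spike_train("d", drift), go[rev(seq_len(nrow(go))), ])
  expect_equal(st3$rho, -st2$rho, tolerance = 1e-8)
  expect_error(trial_stability(u, go[1:10, ]), "20 trials")
})

test_that("significant-proportion time courses are bounded fractions", {
  gen <- cached_default_session(1)
  cl <- data.frame(unit_id = gen$ground_truth$unit_id,
                   type_label = gen$ground_truth$type_label,
                   classifiable = TRUE)
  keep <- gen$ground_truth$type_label == "V" |
    (gen$ground_truth$type_label == "I" & gen$ground_truth$baseline_hz > 0.3)
  tc <- significant_proportion_timecourse(
    gen$session, cl[keep, ], category = "correct_go",
    align_events = "water_on", window = c(0.3, 0.8), n_perm = 300,
    seed = 43)
  expect_true(all(tc$frac_excitation >= 0 & tc$frac_excitation <= 1))
  expect_true(all(tc$frac_excitation + tc$frac_suppression <= 1))
  # type I drinking excitation: elevated fraction after water onset
  t1 <- tc[tc$type_label == "I" & tc$bin_center > 0.1, ]
  tv <- tc[tc$type_label == "V" & tc$bin_center > 0.1, ]
  expect_gt(mean(t1$frac_excitation), mean(tv$frac_excitation))
  expect_gt(mean(t1$frac_excitation), 0.5)
})
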