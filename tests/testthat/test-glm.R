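# A session with long-ish, variable sampling durations shared by the
# encoding-model tests.
glm_fixture_session <- function(n_trials = 140L, seed = 67) {
  cfg <- generator_config(n_units = 1L, n_trials = n_trials,
                          type_proportions = c(I = 0, II = 0, III = 0,
                                               IV = 0, V = 1))
  generate_session(cfg, seed = seed)$session
}

test_that("basis functions partition their window", {
  box <- basis_functions(c(0, 1), 5, "boxcar")
  tt <- seq(0.001, 0.999, by = 0.001)
  B <- box(tt)
  expect_true(all(rowSums(B) == 1))
  expect_true(all(B %in% c(0, 1)))
  expect_equal(colSums(B) / length(tt), rep(0.2, 5), tolerance = 0.01)
  # raised cosine: non-negative, ~partition of unity in the interior
  rc <- basis_functions(c(0, 1), 8, "raised_cosine")
  R <- rc(tt)
  expect_true(all(R >= 0))
  interior <- tt > 2 / 7 & tt < 5 / 7
  expect_equal(rowSums(R[interior, ]), rep(1, sum(interior)),
               tolerance = 0.01)
  # zero outside the window
  expect_true(all(rc(c(-0.5, 1.5)) == 0))
})

test_that("design matrix rows conserve spike counts and span structure", {
  s <- glm_fixture_session()
  u <- s$units[[1]]
  spec <- design_spec(basis_type = "boxcar", n_basis = 4)
  d <- build_design_matrix(u, s, spec)
  go <- trial_category(s$trials, "correct_go")
  # y sums to the spikes inside the analysis spans
  want <- sum(sapply(seq_len(nrow(go)), function(i) {
    span <- c(go$odor_on_s[i] + 0.370, go$port_exit_s[i])
    n_bins <- floor((span[2] - span[1]) / 0.02 + 1e-9)
    hi <- span[1] + n_bins * 0.02
    sum(u$spike_times >= span[1] & u$spike_times < hi)
  }))
  expect_equal(sum(d$y), want)
  expect_true(all(d$X >= 0))
  expect_equal(unique(d$groups), c("odor_onset", "pre_port_exit"))
  # single-boxcar bases are window-occupancy indicators
  spec1 <- design_spec(basis_type = "boxcar", n_basis = 1)
  d1 <- build_design_matrix(u, s, spec1)
  expect_true(all(d1$X[, 1] == as.numeric(d1$t_onset >= 0.370 &
                                            d1$t_onset <= 1.3)))
})

test_that("planted coefficients are recovered with negligible penalty", {
  s <- glm_fixture_session(n_trials = 300L, seed = 71)
  # identifiable design: the kernel windows must not jointly tile every
  # analysis-span bin, otherwise the groups are exactly collinear
  spec <- design_spec(basis_type = "boxcar", n_basis = 3,
                      onset_window = c(0.370, 0.75),
                      exit_window = c(-0.25, 0))
  d <- build_design_matrix(s$units[[1]], s, spec)
  beta <- c(0.8, -0.4, 0.5, 0.3, -0.6, 0.9)
  b0 <- log(2)
  d$y <- with_seed(5, rpois(nrow(d$X), exp(b0 + as.numeric(d$X %*% beta))))
  fit <- fit_glm(d, lambda_grid = 1e-7, seed = 9)
  got <- fit$coefficients[-1]
  expect_lt(sqrt(sum((got - beta)^2) / sum(beta^2)), 0.05)
  expect_gt(fit$r2_full, 0.05)
})

test_that("independent responses have near-zero explained deviance", {
  s <- glm_fixture_session(seed = 73)
  d <- build_design_matrix(s$units[[1]], s,
                           design_spec(basis_type = "boxcar", n_basis = 3))
  d$y <- with_seed(6, rpois(length(d$y), 1.0))
  fit <- suppressWarnings(fit_glm(d, seed = 10))
  expect_lte(fit$r2_full, 0.02)
})

test_that("relative contributions localize the planted source", {
  s <- glm_fixture_session(n_trials = 200L, seed = 79)
  spec <- design_spec(basis_type = "boxcar", n_basis = 3)
  d <- build_design_matrix(s$units[[1]], s, spec)
  onset_cols <- which(d$groups == "odor_onset")
  # unit driven only by the odor-onset kernel
  eta <- as.numeric(d$X[, onset_cols] %*% c(1.2, 0.4, 0.9))
  d$y <- with_seed(7, rpois(length(eta), exp(log(0.15) + eta)))
  fit <- fit_glm(d, seed = 11)
  expect_gt(relative_contribution(fit, "odor_onset"), 0.9)
  expect_equal(sum(fit$relative_contribution), 1)
  expect_true(all(fit$relative_contribution >= 0))
  # removing a predictor group cannot increase held-out deviance explained
  expect_lte(max(fit$r2_reduced), fit$r2_full + 0.01)
})

test_that("psth reconstruction correlates with the observed profile", {
  s <- glm_fixture_session(n_trials = 200L, seed = 83)
  spec <- design_spec(basis_type = "boxcar", n_basis = 4)
  d <- build_design_matrix(s$units[[1]], s, spec)
  onset_cols <- which(d$groups == "odor_onset")
  eta <- as.numeric(d$X[, onset_cols] %*% c(1.5, -0.5, 0.8, 0.2))
  d$y <- with_seed(8, rpois(length(eta), exp(log(0.4) + eta)))
  fit <- fit_glm(d, seed = 12)
  r_on <- psth_reconstruction_r(fit, "odor_on")
  expect_gt(r_on, 0.8)
  # r is an ordinary Pearson correlation of the two averaged profiles
  lagc <- round(fit$design$t_onset / 0.02)
  obs <- tapply(fit$design$y, lagc, mean)
  pred <- tapply(fit$cv_mu, lagc, mean)
  n <- tapply(fit$design$y, lagc, length)
  ok <- n >= max(3, median(n) / 4)
  expect_equal(r_on, cor(obs[ok], pred[ok]))
  # shuffled predictions carry no signal
  fit2 <- fit
  fit2$cv_mu <- with_seed(13, sample(fit$cv_mu))
  expect_lt(abs(psth_reconstruction_r(fit2, "odor_on")), 0.35)
})
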