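# Direct construction of a population matrix for closed-form cases.
fake_pm <- function(arr, bin_width = 0.02, t0 = -0.5) {
  structure(arr,
            bin_centers = seq(t0 + bin_width / 2, by = bin_width,
                              length.out = dim(arr)[2]),
            conditions = c("correct_go", "correct_no_go")[seq_len(dim(arr)[3])],
            unit_ids = sprintf("u%02d", seq_len(dim(arr)[1])),
            norm_mean = rep(0, dim(arr)[1]), norm_sd = rep(1, dim(arr)[1]),
            normalization = "zscore", class = "population_matrix")
}

test_that("population matrix has the right shape and normalization", {
  gen <- cached_default_session(1)
  pm <- build_population_matrix(gen$session, window = c(0.3, 0.8))
  expect_equal(length(dim(pm)), 3L)
  expect_equal(dim(pm)[3], 2L)
  expect_equal(dim(pm)[1], 100L)
  # z-scored rows: mean 0, sd 1 over concatenated conditions
  m <- matrix(unclass(pm), nrow = dim(pm)[1])
  expect_equal(rowMeans(m), rep(0, 100), tolerance = 1e-10)
  sds <- apply(m, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-8 | sds == 0))
  # de-normalization recovers the raw averages
  raw <- build_population_matrix(gen$session, window = c(0.3, 0.8),
                                 normalization = "raw")
  expect_equal(denormalize_population_matrix(pm), unclass(raw),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a constant-rate unit z-scores to zeros", {
  tr <- tiny_trials()
  tr <- rbind(tr, tr)  # 2 go + 2 no-go correct after category filtering
  for (i in 5:8) {
    shift <- 60 + 15 * (i - 5)
    for (col in grep("_s$", names(tr))) {
      tr[[col]][i] <- tr[[col]][i - 4] + shift
    }
    tr$trial_id[i] <- i
  }
  u <- spike_train("c", seq(0.01, 130, by = 0.02))  # exactly 1 spike/bin
  s <- gng_session("cs", list(u), tr)
  pm <- build_population_matrix(s, window = c(0.2, 0.4), min_trials = 2)
  expect_equal(as.numeric(unclass(pm)), rep(0, dim(pm)[2] * 2))
})

test_that("pca subspace is orthonormal and matches an eigen oracle", {
  set.seed(97)
  arr <- array(rnorm(10 * 20 * 2), dim = c(10, 20, 2))
  pm <- fake_pm(arr)
  sub <- pca_subspace(pm, k = 3)
  expect_equal(crossprod(sub$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  evr <- sub$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-9)
  # independent dense eigendecomposition of the covariance
  X <- t(matrix(arr, nrow = 10))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1))
  expect_equal(abs(sum(sub$loadings[, 1] * ev$vectors[, 1])), 1,
               tolerance = 1e-8)
  expect_equal(evr, ev$values / sum(ev$values), tolerance = 1e-8)
  # rank-2 data: third component explains nothing
  basis2 <- matrix(rnorm(10 * 2), 10, 2)
  arr2 <- array(basis2 %*% matrix(rnorm(2 * 40), 2, 40), dim = c(10, 20, 2))
  sub2 <- pca_subspace(fake_pm(arr2), k = 2)
  expect_lt(sub2$explained_variance_ratio[3], 1e-10)
  expect_error(pca_subspace(fake_pm(arr2), k = 5), "rank")
})

test_that("trajectory distance obeys closed forms and flags divergence", {
  arr <- array(0, dim = c(4, 50, 2))
  pm0 <- fake_pm(arr)
  d0 <- trajectory_distance(pm0, baseline_window = c(-0.5, -0.1))
  expect_equal(d0$value, rep(0, 50))
  expect_false(any(d0$significant))
  # a single unit differing by d in one bin gives distance |d| there
  arr[2, 40, 1] <- -3.7
  d1 <- trajectory_distance(fake_pm(arr), baseline_window = c(-0.5, -0.1))
  expect_equal(d1$value[40], 3.7)
  expect_equal(sum(d1$value), 3.7)
  expect_true(d1$significant[40])
  expect_error(trajectory_distance(pm0, baseline_window = c(-0.5, -0.47)),
               "baseline bins")
  # distance in the full space dominates any projection (contraction)
  set.seed(101)
  arr3 <- array(rnorm(8 * 50 * 2, sd = 0.1), dim = c(8, 50, 2))
  arr3[, 26:50, 1] <- arr3[, 26:50, 1] + 1
  pm3 <- fake_pm(arr3)
  sub3 <- pca_subspace(pm3, k = 2)
  d_full <- trajectory_distance(pm3, baseline_window = c(-0.5, -0.1))
  d_sub <- trajectory_distance(pm3, subspace = sub3,
                               baseline_window = c(-0.5, -0.1))
  expect_true(all(d_full$value >= d_sub$value - 1e-9))
})

test_that("distance and velocity are invariant to unit order and rotation", {
  set.seed(103)
  arr <- array(rnorm(6 * 40 * 2), dim = c(6, 40, 2))
  pm <- fake_pm(arr, t0 = -0.4)
  d <- trajectory_distance(pm, baseline_window = c(-0.4, -0.1))
  v <- trajectory_velocity(pm, 1, baseline_window = c(-0.4, -0.1))
  perm <- sample(6)
  pm_p <- fake_pm(arr[perm, , ], t0 = -0.4)
  expect_equal(trajectory_distance(pm_p,
                                   baseline_window = c(-0.4, -0.1))$value,
               d$value)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  arr_r <- array(apply(arr, 3, function(m) Q %*% m), dim = dim(arr))
  pm_r <- fake_pm(arr_r, t0 = -0.4)
  expect_equal(trajectory_distance(pm_r,
                                   baseline_window = c(-0.4, -0.1))$value,
               d$value, tolerance = 1e-10)
  expect_equal(trajectory_velocity(pm_r, 1,
                                   baseline_window = c(-0.4, -0.1))$value,
               v$value, tolerance = 1e-10)
})

test_that("trajectory velocity matches closed forms", {
  arr <- array(2.5, dim = c(3, 60, 2))
  v0 <- trajectory_velocity(fake_pm(arr), 1,
                            baseline_window = c(-0.5, -0.1))
  expect_equal(v0$value, rep(0, length(v0$value)))
  # linear ramp of slope s in one unit: velocity |s|
  s_ <- 4
  arr[1, , 1] <- s_ * seq(0.01, by = 0.02, length.out = 60)
  v1 <- trajectory_velocity(fake_pm(arr), 1,
                            baseline_window = c(-0.5, -0.1))
  expect_equal(v1$value, rep(s_, length(v1$value)), tolerance = 1e-9)
})

test_that("neural weights reflect unit contributions", {
  set.seed(107)
  arr <- array(rnorm(8 * 30 * 2, sd = 0.2), dim = c(8, 30, 2))
  arr[5, , ] <- arr[5, , ] * 0  # zero-variance unit
  arr[3, 16:30, ] <- arr[3, 16:30, ] + 10  # dominant planted unit
  sub <- pca_subspace(fake_pm(arr), k = 2)
  w <- neural_weights(sub, 1)
  expect_true(all(w >= 0))
  expect_equal(which.max(w), 3L, ignore_attr = TRUE)
  expect_lt(w[5], 0.05)
  # invariant to a sign flip of the component
  sub2 <- sub
  sub2$loadings[, 1] <- -sub2$loadings[, 1]
  expect_equal(neural_weights(sub2, 1), w)
})

test_that("sliding weights are bounded and track transient contributors", {
  set.seed(109)
  arr <- array(rnorm(6 * 50 * 2, sd = 0.3), dim = c(6, 50, 2))
  arr[2, 40:50, ] <- arr[2, 40:50, ] + 8  # late transient in unit 2
  sw <- sliding_weights(fake_pm(arr))
  expect_true(all(sw >= 0 & sw <= 1, na.rm = TRUE))
  centers <- attr(sw, "bin_centers")
  late <- which(centers > 0.3)
  expect_equal(unname(which.max(rowMeans(sw[, late]))), 2L)
})

test_that("weight comparison across types is a standard one-way ANOVA", {
  set.seed(113)
  w <- c(rnorm(12, 1), rnorm(12, 1.1))
  g <- rep(c("I", "V"), each = 12)
  res <- compare_weights_by_type(w, g)
  tt <- t.test(w[g == "I"], w[g == "V"], var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  # planted +2 SD shift is detected
  w2 <- c(rnorm(15, 3, 1), rnorm(15, 1, 1), rnorm(15, 1, 1))
  g2 <- rep(c("I", "II", "V"), each = 15)
  res2 <- compare_weights_by_type(w2, g2)
  expect_lt(res2$p_value, 0.01)
  expect_lt(res2$tukey["II-I", "p adj"], 0.05)
  expect_error(compare_weights_by_type(rnorm(10), rep("I", 10)),
               "two types")
})

test_that("planted population divergence is flagged at the planted time", {
  set.seed(127)
  n_units <- 40
  centers0 <- seq(-0.49, 0.99, by = 0.02)
  n_bins <- length(centers0)
  arr <- array(rnorm(n_units * n_bins * 2, sd = 0.3),
               dim = c(n_units, n_bins, 2))
  # conditions diverge from 450 ms
  bump <- pmax(0, (centers0 - 0.45) / 0.1)
  bump <- pmin(bump, 1.5)
  for (u in 1:20) arr[u, , 1] <- arr[u, , 1] + bump
  pm <- fake_pm(arr)
  d <- trajectory_distance(pm, baseline_window = c(-0.45, -0.05))
  first <- d$bin_center[which(d$significant)[1]]
  expect_gte(first, 0.40)
  expect_lte(first, 0.55)
  v <- trajectory_velocity(pm, 1, baseline_window = c(-0.45, -0.05))
  expect_gt(max(v$value[v$bin_center > 0.4 & v$bin_center < 0.7]),
            attr(v, "baseline_mean") + 2 * attr(v, "baseline_sd"))
})
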