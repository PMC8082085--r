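# Encoding model: ridge-penalized Poisson regression of single-unit spike
# counts on task-event kernels, with cross-validated deviance-explained and
# per-variable relative contributions by variance loss on removal.

#' Basis functions over an event-anchored window
#'
#' `"raised_cosine"`: overlapping raised-cosine bumps tiling the window
#' (partition of unity away from the edges). `"boxcar"`: adjacent
#' indicator functions partitioning the window exactly.
#'
#' @param window `c(start, end)` seconds relative to the anchor event.
#' @param n_basis number of basis functions.
#' @param type `"raised_cosine"` or `"boxcar"`.
#' @return function `f(t)` mapping times-from-anchor to a
#'   `length(t) x n_basis` non-negative matrix (zero outside the window).
#' @export
basis_functions <- function(window, n_basis = 8L,
                            type = c("raised_cosine", "boxcar")) {
  type <- match.arg(type)
  stopifnot(window[2] > window[1], n_basis >= 1)
  if (type == "boxcar") {
    edges <- seq(window[1], window[2], length.out = n_basis + 1L)
    return(function(t) {
      out <- matrix(0, length(t), n_basis)
      idx <- findInterval(t, edges, left.open = FALSE)
      idx[t >= edges[n_basis + 1L]] <- 0L
      ok <- idx >= 1L & idx <= n_basis
      out[cbind(which(ok), idx[ok])] <- 1
      out
    })
  }
  centers <- seq(window[1], window[2], length.out = n_basis)
  d <- if (n_basis > 1) centers[2] - centers[1] else diff(window)
  function(t) {
    out <- matrix(0, length(t), n_basis)
    for (j in seq_len(n_basis)) {
      u <- t - centers[j]
      in_sup <- abs(u) < 2 * d & t >= window[1] & t <= window[2]
      # 0.25*(1+cos) so that the interior sum over bumps is ~1
      out[in_sup, j] <- 0.25 * (1 + cos(pi * u[in_sup] / (2 * d)))
    }
    out
  }
}

#' Encoding-model design specification
#'
#' The analysis span of each correct go trial runs from
#' `odor_on + span_start` (370 ms by default, the median go-cue excitation
#' onset) to the odor-port exit. Two predictor groups are used: a kernel
#' anchored at odor onset and a kernel anchored (with a negative window)
#' at the odor-port exit.
#'
#' @param bin_width response bin width (s).
#' @param span_start start of the analysis span after odor onset (s).
#' @param onset_window,exit_window kernel windows relative to their
#'   anchors.
#' @param n_basis basis functions per variable.
#' @param basis_type see [basis_functions()].
#' @return A `design_spec` list.
#' @export
design_spec <- function(bin_width = 0.020, span_start = 0.370,
                        onset_window = c(0.370, 1.3),
                        exit_window = c(-0.8, 0),
                        n_basis = 8L,
                        basis_type = c("raised_cosine", "boxcar")) {
  basis_type <- match.arg(basis_type)
  variables <- list(
    odor_onset = list(anchor = "odor_on", window = onset_window),
    pre_port_exit = list(anchor = "port_exit", window = exit_window))
  structure(list(bin_width = bin_width, span_start = span_start,
                 variables = variables, n_basis = n_basis,
                 basis_type = basis_type),
            class = "design_spec")
}

#' Build the encoding-model design matrix for one unit
#'
#' Rows are the concatenated analysis-span bins of the correct go trials;
#' `y` holds the spike count per bin; `X` holds each variable's basis
#' functions evaluated at the bin center's lag from that variable's anchor
#' event.
#'
#' @param unit a [spike_train()].
#' @param session a [gng_session()].
#' @param spec a [design_spec()].
#' @param min_trials minimum usable correct go trials.
#' @return list: `X`, `y`, `groups` (variable name per column), `trial`
#'   (trial id per row), `t_onset`/`t_exit` (bin-center lags from the two
#'   anchors), `n_dropped` (trials with an empty span).
#' @export
build_design_matrix <- function(unit, session, spec = design_spec(),
                                min_trials = 20L) {
  go <- trial_category(session$trials, "correct_go")
  bw <- spec$bin_width
  bases <- lapply(spec$variables, function(v) {
    basis_functions(v$window, spec$n_basis, spec$basis_type)
  })
  rows_X <- list(); rows_y <- list(); trial_of <- list()
  t_on <- list(); t_ex <- list()
  n_dropped <- 0L
  st <- unit$spike_times
  for (i in seq_len(nrow(go))) {
    tr <- go[i, ]
    span <- c(tr$odor_on_s + spec$span_start, tr$port_exit_s)
    n_bins <- floor((span[2] - span[1]) / bw + 1e-9)
    if (n_bins < 1L) { n_dropped <- n_dropped + 1L; next }
    edges <- span[1] + bw * (0:n_bins)
    centers <- edges[-length(edges)] + bw / 2
    y <- tabulate(findInterval(st[st >= edges[1] & st < edges[n_bins + 1]],
                               edges), nbins = n_bins)
    lag_on <- centers - tr$odor_on_s
    lag_ex <- centers - tr$port_exit_s
    Xi <- cbind(bases$odor_onset(lag_on), bases$pre_port_exit(lag_ex))
    rows_X[[length(rows_X) + 1L]] <- Xi
    rows_y[[length(rows_y) + 1L]] <- y
    trial_of[[length(trial_of) + 1L]] <- rep(tr$trial_id, n_bins)
    t_on[[length(t_on) + 1L]] <- lag_on
    t_ex[[length(t_ex) + 1L]] <- lag_ex
  }
  if (length(rows_y) < min_trials) {
    stop("unit '", unit$unit_id, "': fewer than ", min_trials,
         " usable correct go trials", call. = FALSE)
  }
  X <- do.call(rbind, rows_X)
  colnames(X) <- paste0(rep(names(spec$variables), each = spec$n_basis),
                        "_b", seq_len(spec$n_basis))
  list(X = X, y = unlist(rows_y),
       groups = rep(names(spec$variables), each = spec$n_basis),
       trial = unlist(trial_of), t_onset = unlist(t_on),
       t_exit = unlist(t_ex), bin_width = bw, n_dropped = n_dropped)
}

poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

ridge_poisson_cv <- function(X, y, foldid, lambda_grid, seed) {
  # returns held-out predictions and deviance-explained R2
  folds <- sort(unique(foldid))
  mu_cv <- rep(NA_real_, length(y))
  for (f in folds) {
    test <- foldid == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    inner <- with_seed(child_seed(seed, f), {
      # inner lambda selection on the training block
      infold <- sample(rep_len(1:4, sum(!test)))
      dev_by_lambda <- sapply(lambda_grid, function(lam) {
        d <- 0
        for (g in 1:4) {
          it <- infold == g
          fit <- glmnet::glmnet(Xtr[!it, , drop = FALSE], ytr[!it],
                                family = "poisson", alpha = 0,
                                lambda = lam, standardize = TRUE)
          mu <- as.numeric(stats::predict(fit, Xtr[it, , drop = FALSE],
                                          type = "response"))
          d <- d + poisson_deviance(ytr[it], mu)
        }
        d
      })
      lambda_grid[which.min(dev_by_lambda)]
    })
    fit <- glmnet::glmnet(Xtr, ytr, family = "poisson", alpha = 0,
                          lambda = inner, standardize = TRUE)
    mu_cv[test] <- as.numeric(stats::predict(fit, X[test, , drop = FALSE],
                                             type = "response"))
  }
  mu_cv
}

#' Fit the ridge-penalized Poisson encoding model
#'
#' Cross-validation is by trial blocks: whole trials are held out together.
#' The ridge penalty is chosen per outer fold on inner folds from a small
#' fixed grid. "Explained variance" is the cross-validated fraction of
#' Poisson deviance explained relative to the intercept-only model; the
#' per-variable reduced models refit the same folds with that variable's
#' columns removed.
#'
#' @param design list from [build_design_matrix()].
#' @param cv_folds number of outer folds (by trial).
#' @param lambda_grid ridge penalties searched on the inner folds.
#' @param seed integer seed (fold assignment and inner selection).
#' @return A `glm_fit` list: `coefficients` (full-data fit), `r2_full`,
#'   `r2_reduced` (named by variable), `relative_contribution`,
#'   `cv_mu` (held-out mean predictions per row), `design`.
#' @export
fit_glm <- function(design, cv_folds = 5L,
                    lambda_grid = 10^seq(-4, 0, length.out = 5),
                    seed = 1L) {
  X <- design$X; y <- design$y
  if (nrow(X) <= 10 * ncol(X)) {
    warning("few rows relative to predictors; fit may be unstable",
            call. = FALSE)
  }
  trials <- unique(design$trial)
  fold_of_trial <- with_seed(child_seed(seed, 0L),
                             sample(rep_len(seq_len(cv_folds),
                                            length(trials))))
  foldid <- fold_of_trial[match(design$trial, trials)]
  null_dev <- vapply(seq_len(cv_folds), function(f) {
    test <- foldid == f
    poisson_deviance(y[test], rep(mean(y[!test]), sum(test)))
  }, numeric(1))
  cv_r2 <- function(cols, salt) {
    mu <- ridge_poisson_cv(X[, cols, drop = FALSE], y, foldid, lambda_grid,
                           seed = child_seed(seed, salt))
    dev <- vapply(seq_len(cv_folds), function(f) {
      poisson_deviance(y[foldid == f], mu[foldid == f])
    }, numeric(1))
    list(r2 = 1 - sum(dev) / sum(null_dev), mu = mu)
  }
  full <- cv_r2(seq_len(ncol(X)), 1L)
  vars <- unique(design$groups)
  r2_red <- vapply(seq_along(vars), function(i) {
    cv_r2(which(design$groups != vars[i]), 1L + i)$r2
  }, numeric(1))
  names(r2_red) <- vars
  # full-data coefficients at the median grid penalty
  fit_all <- glmnet::glmnet(X, y, family = "poisson", alpha = 0,
                            lambda = stats::median(lambda_grid),
                            standardize = TRUE)
  drops <- pmax(0, full$r2 - r2_red)
  contrib <- if (sum(drops) > 0) drops / sum(drops) else {
    warning("no variable contributes; uniform fractions", call. = FALSE)
    rep(1 / length(drops), length(drops))
  }
  names(contrib) <- vars
  structure(list(coefficients = as.numeric(stats::coef(fit_all)),
                 r2_full = full$r2, r2_reduced = r2_red,
                 relative_contribution = contrib,
                 cv_mu = full$mu, foldid = foldid, design = design),
            class = "glm_fit")
}

#' Relative contribution of one variable
#'
#' `max(0, R2_full - R2_without_v)`, normalized over variables.
#'
#' @param fit a `glm_fit`.
#' @param variable variable name (omit for all).
#' @return named fraction(s) summing to 1 over all variables.
#' @export
relative_contribution <- function(fit, variable = NULL) {
  rc <- fit$relative_contribution
  if (is.null(variable)) rc else rc[[variable]]
}

#' Correlation between predicted and observed aligned PSTHs
#'
#' Held-out (cross-validated) per-bin predictions and observed counts are
#' averaged on a lag grid relative to the chosen anchor; the Pearson
#' correlation of the two averaged rate profiles is returned.
#'
#' @param fit a `glm_fit`.
#' @param align_event `"odor_on"` or `"port_exit"`.
#' @param grid_width averaging bin width (s) on the lag axis.
#' @return Pearson r (`NA` when either profile is constant).
#' @export
psth_reconstruction_r <- function(fit, align_event = c("odor_on",
                                                       "port_exit"),
                                  grid_width = 0.020) {
  align_event <- match.arg(align_event)
  lag <- if (align_event == "odor_on") fit$design$t_onset else
    fit$design$t_exit
  cell <- round(lag / grid_width)
  obs <- tapply(fit$design$y, cell, mean)
  pred <- tapply(fit$cv_mu, cell, mean)
  n <- tapply(fit$design$y, cell, length)
  ok <- n >= max(3, stats::median(n) / 4)
  if (stats::sd(obs[ok]) == 0 || stats::sd(pred[ok]) == 0) return(NA_real_)
  stats::cor(obs[ok], pred[ok])
}

#' Fit the encoding model for many units
#'
#' @param units list of [spike_train()]s.
#' @param session a [gng_session()].
#' @param spec a [design_spec()].
#' @param seed integer seed, fanned out per unit.
#' @param ... forwarded to [fit_glm()].
#' @return data.frame: `unit_id`, `r2_full`, `contrib_odor_onset`,
#'   `contrib_pre_exit`, `r_onset_aligned`, `r_exit_aligned`.
#' @export
encode_units <- function(units, session, spec = design_spec(), seed = 1L,
                         ...) {
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    design <- build_design_matrix(u, session, spec)
    fit <- fit_glm(design, seed = child_seed(seed, i), ...)
    data.frame(unit_id = u$unit_id, r2_full = fit$r2_full,
               contrib_odor_onset = fit$relative_contribution[["odor_onset"]],
               contrib_pre_exit =
                 fit$relative_contribution[["pre_port_exit"]],
               r_onset_aligned = psth_reconstruction_r(fit, "odor_on"),
               r_exit_aligned = psth_reconstruction_r(fit, "port_exit"))
  })
  do.call(rbind, rows)
}
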