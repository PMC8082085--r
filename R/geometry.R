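# Population trajectory geometry: pseudopopulation response matrix, PCA
# subspaces, condition separation distance, trajectory velocity with
# baseline-derived significance bands, and per-neuron weights.

#' Assemble a normalized population response matrix
#'
#' Units are pooled across sessions into a pseudopopulation. For each unit
#' and condition the trial-averaged, Gaussian-smoothed rate on a common
#' aligned bin grid is computed, then each unit is z-scored over its
#' concatenated condition time courses (zero-variance units become all
#' zeros). The normalization is recorded so raw averages can be recovered.
#'
#' @param sessions a [gng_session()] or list of them.
#' @param categories trial categories defining the conditions (default
#'   correct go and correct no-go).
#' @param align_event alignment event stem.
#' @param window `c(pre, post)` seconds around the event.
#' @param bin_width,kernel_sd binning and smoothing parameters.
#' @param normalization `"zscore"` (default) or `"raw"`.
#' @param min_trials a unit must have at least this many trials in every
#'   condition; others are excluded (count in attribute `n_excluded`).
#' @return A `population_matrix`: array units x bins x conditions with
#'   attributes `bin_centers`, `conditions`, `unit_ids`, `norm_mean`,
#'   `norm_sd`.
#' @export
build_population_matrix <- function(sessions,
                                    categories = c("correct_go",
                                                   "correct_no_go"),
                                    align_event = "odor_on",
                                    window = c(0.5, 1.0),
                                    bin_width = 0.020, kernel_sd = 0.060,
                                    normalization = c("zscore", "raw"),
                                    min_trials = 5L) {
  normalization <- match.arg(normalization)
  if (inherits(sessions, "gng_session")) sessions <- list(sessions)
  rows <- list(); ids <- character(0); n_excluded <- 0L
  for (s in sessions) {
    tr_by_cat <- lapply(categories, trial_category, trials = s$trials)
    for (u in s$units) {
      if (any(vapply(tr_by_cat, nrow, integer(1)) < min_trials)) {
        n_excluded <- n_excluded + 1L
        next
      }
      avgs <- lapply(tr_by_cat, function(tr) {
        colMeans(unclass(smooth_psth(
          align_and_bin(u, tr, align_event, window, bin_width), kernel_sd)))
      })
      rows[[length(rows) + 1L]] <- unlist(avgs)
      ids <- c(ids, paste0(s$session_id, "/", u$unit_id))
    }
  }
  if (!length(rows)) stop("no units with enough trials", call. = FALSE)
  m <- do.call(rbind, rows)
  n_bins <- ncol(m) / length(categories)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  # zero-variance guard with a relative tolerance (exactly constant rows
  # can carry ~1e-14 floating-point jitter)
  flat <- sdv <= 1e-10 * pmax(abs(mu), 1)
  sdv[flat] <- 0
  if (normalization == "zscore") {
    scl <- ifelse(sdv > 0, sdv, 1)
    m <- (m - mu) / scl
    m[flat, ] <- 0
  }
  arr <- array(m, dim = c(nrow(m), n_bins, length(categories)))
  centers <- seq(-window[1] + bin_width / 2, by = bin_width,
                 length.out = n_bins)
  structure(arr, bin_centers = centers, conditions = categories,
            unit_ids = ids, norm_mean = mu, norm_sd = sdv,
            normalization = normalization, n_excluded = n_excluded,
            class = "population_matrix")
}

#' Undo the per-unit normalization of a population matrix
#' @param pm a `population_matrix`.
#' @return array of raw trial-averaged rates (Hz).
#' @export
denormalize_population_matrix <- function(pm) {
  if (attr(pm, "normalization") == "raw") return(unclass(pm))
  mu <- attr(pm, "norm_mean"); sdv <- attr(pm, "norm_sd")
  scl <- ifelse(sdv > 0, sdv, 1)
  arr <- unclass(pm)
  sweep(sweep(arr, 1, scl, "*"), 1, mu, "+")
}

#' Principal-component subspace of the population response
#'
#' PCA is fitted jointly on both conditions: observations are the
#' concatenated condition time bins, variables are the units. Loadings are
#' orthonormal; condition trajectories are the projections.
#'
#' @param pm a `population_matrix`.
#' @param k number of components (default 3).
#' @return A `pc_subspace` list: `loadings` (units x k),
#'   `explained_variance_ratio`, `trajectories` (array k x bins x
#'   conditions), `bin_centers`, `conditions`.
#' @export
pca_subspace <- function(pm, k = 3L) {
  arr <- unclass(pm)
  n_units <- dim(arr)[1]
  if (n_units < k) stop("fewer units than requested components",
                        call. = FALSE)
  X <- t(matrix(arr, nrow = n_units))       # (bins*conds) x units
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (k > sum(pc$sdev > 1e-12)) stop("k exceeds the rank of the data",
                                     call. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  traj <- array(t(scores), dim = c(k, dim(arr)[2], dim(arr)[3]))
  structure(list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance_ratio = evr,
                 trajectories = traj,
                 bin_centers = attr(pm, "bin_centers"),
                 conditions = attr(pm, "conditions"),
                 unit_ids = attr(pm, "unit_ids")),
            class = "pc_subspace")
}

baseline_band <- function(values, centers, baseline_window, min_bins = 3L) {
  idx <- centers >= baseline_window[1] & centers <= baseline_window[2]
  if (sum(idx) < min_bins) stop("need at least ", min_bins,
                                " baseline bins", call. = FALSE)
  c(mean = mean(values[idx]), sd = stats::sd(values[idx]))
}

geometry_trace <- function(kind, centers, values, baseline_window) {
  bb <- baseline_band(values, centers, baseline_window)
  structure(data.frame(bin_center = centers, value = values,
                       significant = values > bb["mean"] + 2 * bb["sd"]),
            kind = kind, baseline_mean = unname(bb["mean"]),
            baseline_sd = unname(bb["sd"]),
            baseline_window = baseline_window,
            class = c("geometry_trace", "data.frame"))
}

#' Separation between condition population trajectories
#'
#' Per-bin Euclidean distance between the two conditions' population
#' vectors, computed in the full normalized space (default) or in a fitted
#' PC subspace. Bins whose value exceeds the baseline mean + 2 SD are
#' flagged.
#'
#' @param pm a `population_matrix` with exactly two conditions.
#' @param subspace optional `pc_subspace`; when supplied the distance is
#'   computed between projected trajectories.
#' @param baseline_window `c(start, end)` seconds (relative to the
#'   alignment event) defining the baseline bins.
#' @return A `geometry_trace` data.frame (`bin_center`, `value`,
#'   `significant`) with baseline attributes.
#' @export
trajectory_distance <- function(pm, subspace = NULL,
                                baseline_window = c(-0.45, -0.05)) {
  if (dim(pm)[3] != 2) stop("distance needs exactly two conditions",
                            call. = FALSE)
  if (is.null(subspace)) {
    d <- sqrt(colSums((unclass(pm)[, , 1] - unclass(pm)[, , 2])^2))
  } else {
    tr <- subspace$trajectories
    d <- sqrt(colSums((tr[, , 1, drop = FALSE] - tr[, , 2, drop = FALSE])^2))
  }
  geometry_trace("distance", attr(pm, "bin_centers"), as.numeric(d),
                 baseline_window)
}

#' Rate of change (velocity) of a population trajectory
#'
#' `||x(t + width) - x(t)|| / width` at each sliding step for one
#' condition, reported at the midpoint `t + width/2`, with a baseline band
#' as in [trajectory_distance()].
#'
#' @param pm a `population_matrix`.
#' @param condition condition name or index.
#' @param width,step sliding parameters (s).
#' @inheritParams trajectory_distance
#' @return A `geometry_trace`.
#' @export
trajectory_velocity <- function(pm, condition = 1L, width = 0.100,
                                step = 0.020,
                                baseline_window = c(-0.45, -0.05)) {
  conds <- attr(pm, "conditions")
  if (is.character(condition)) condition <- match(condition, conds)
  x <- unclass(pm)[, , condition]
  centers <- attr(pm, "bin_centers")
  bw <- centers[2] - centers[1]
  lag <- round(width / bw)
  stride <- max(1L, round(step / bw))
  if (lag < 1) stop("width must cover at least one bin", call. = FALSE)
  i0 <- seq(1L, ncol(x) - lag, by = stride)
  v <- sqrt(colSums((x[, i0 + lag, drop = FALSE] -
                     x[, i0, drop = FALSE])^2)) / width
  geometry_trace("velocity", centers[i0] + width / 2, as.numeric(v),
                 baseline_window)
}

#' Per-unit weights in a principal component
#'
#' Absolute PCA loadings: the contribution of each unit to one dimension
#' of the population subspace.
#'
#' @param subspace a `pc_subspace`.
#' @param dimension component index (default 1).
#' @return named non-negative numeric vector, one weight per unit.
#' @export
neural_weights <- function(subspace, dimension = 1L) {
  w <- abs(subspace$loadings[, dimension])
  names(w) <- subspace$unit_ids
  w
}

#' Sliding-window neural weights
#'
#' PCA is refitted within each sliding window (both conditions jointly);
#' the absolute first-component loading per unit tracks each unit's
#' contribution over time.
#'
#' @param pm a `population_matrix`.
#' @param width,step sliding parameters (s).
#' @return matrix units x windows of `|PC1 loading|`, with window centers
#'   in attribute `bin_centers` (degenerate windows give `NA`).
#' @export
sliding_weights <- function(pm, width = 0.100, step = 0.020) {
  arr <- unclass(pm)
  centers <- attr(pm, "bin_centers")
  bw <- centers[2] - centers[1]
  span <- max(1L, round(width / bw))
  stride <- max(1L, round(step / bw))
  i0 <- seq(1L, dim(arr)[2] - span + 1L, by = stride)
  out <- matrix(NA_real_, nrow = dim(arr)[1], ncol = length(i0))
  for (j in seq_along(i0)) {
    bins <- i0[j]:(i0[j] + span - 1L)
    X <- t(matrix(arr[, bins, , drop = FALSE], nrow = dim(arr)[1]))
    X <- scale(X, center = TRUE, scale = FALSE)
    if (all(abs(X) < 1e-12)) next
    sv <- svd(X, nu = 0, nv = 1)
    out[, j] <- abs(sv$v[, 1])
  }
  rownames(out) <- attr(pm, "unit_ids")
  attr(out, "bin_centers") <- centers[i0] + (span - 1L) * bw / 2
  out
}

#' Compare neural weights across neuron types
#'
#' One-way ANOVA of weight by type with Tukey HSD pairwise comparisons.
#'
#' @param weights numeric vector of per-unit weights.
#' @param type_labels factor/character of the same length.
#' @param min_units types with fewer units are dropped.
#' @return list: `f_statistic`, `p_value`, `tukey` (pairwise table),
#'   `group_means`.
#' @export
compare_weights_by_type <- function(weights, type_labels, min_units = 3L) {
  keep_types <- names(which(table(type_labels) >= min_units))
  keep <- type_labels %in% keep_types
  weights <- weights[keep]
  g <- factor(type_labels[keep])
  if (nlevels(g) < 2) stop("need at least two types with enough units",
                           call. = FALSE)
  fit <- stats::aov(weights ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(f_statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
       tukey = as.data.frame(tk),
       group_means = tapply(weights, g, mean))
}
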