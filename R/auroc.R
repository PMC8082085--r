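# Trial-wise ROC discriminability and its permutation test — the core
# response statistics every downstream stage is built on.

#' Area under the ROC curve for two rate samples
#'
#' Probability that a value drawn from `a` exceeds one drawn from `b`, ties
#' counted one half — equivalently the Mann–Whitney U statistic divided by
#' `n_a * n_b`. 0.5 means no discrimination; values above 0.5 mean `a`
#' tends larger.
#'
#' @param a,b numeric samples (both non-empty).
#' @return auROC in `[0, 1]`, with `auroc(a, b) + auroc(b, a) = 1`.
#' @export
auroc <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  r <- rank(c(a, b))
  (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
    (length(a) * length(b))
}

# Deviations |auROC - 0.5| for n_perm random relabelings, computed from
# pooled mid-ranks (which are invariant under relabeling).
perm_deviations <- function(r, n_a, n_b, n_perm) {
  n <- n_a + n_b
  sums <- vapply(seq_len(n_perm),
                 function(i) sum(r[sample.int(n, n_a)]), numeric(1))
  abs((sums - n_a * (n_a + 1) / 2) / (n_a * n_b) - 0.5)
}

#' Two-sided permutation p value for an auROC
#'
#' The null distribution is obtained by relabeling trials; extremeness is
#' measured as `|auROC - 0.5|`. The Monte-Carlo estimate uses add-one
#' smoothing, `p = (1 + k) / (1 + n_perm)`, so `p` is always in `(0, 1]`.
#' With `exact = TRUE` all label assignments are enumerated instead
#' (feasible for small samples) and `p` is the exact tail fraction.
#'
#' @param a,b numeric samples.
#' @param n_perm number of relabelings (>= 100) for the Monte-Carlo test.
#' @param seed optional seed for the relabelings.
#' @param exact enumerate all `choose(n_a + n_b, n_a)` splits.
#' @return p value in `(0, 1]`.
#' @export
permutation_pvalue <- function(a, b, n_perm = 1000L, seed = NULL,
                               exact = FALSE) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  obs <- abs((sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2) / (n_a * n_b) - 0.5)
  tol <- 1e-12
  if (exact) {
    splits <- utils::combn(n_a + n_b, n_a)
    sums <- colSums(matrix(r[splits], nrow = n_a))
    dev <- abs((sums - n_a * (n_a + 1) / 2) / (n_a * n_b) - 0.5)
    return(mean(dev >= obs - tol))
  }
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  dev <- with_seed(seed, perm_deviations(r, n_a, n_b, n_perm))
  (1 + sum(dev >= obs - tol)) / (1 + n_perm)
}

#' auROC with permutation significance and response direction
#'
#' @inheritParams permutation_pvalue
#' @param alpha significance level (default 0.01, per-bin, uncorrected).
#' @return An `auroc_result` list: `auroc`, `p_value`, `n_a`, `n_b`,
#'   `direction` (`"excitation"` if significant with auROC > 0.5,
#'   `"suppression"` if significant with auROC < 0.5, else `"none"`).
#' @export
auroc_test <- function(a, b, n_perm = 1000L, seed = NULL, alpha = 0.01,
                       exact = FALSE) {
  val <- auroc(a, b)
  p <- permutation_pvalue(a, b, n_perm = n_perm, seed = seed, exact = exact)
  direction <- if (p < alpha && val > 0.5) "excitation"
    else if (p < alpha && val < 0.5) "suppression" else "none"
  structure(list(auroc = val, p_value = p, n_a = length(a), n_b = length(b),
                 direction = direction),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("<auroc_result> auROC = %.3f, p = %.4g (n = %d vs %d), %s\n",
              x$auroc, x$p_value, x$n_a, x$n_b, x$direction))
  invisible(x)
}
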