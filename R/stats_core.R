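#' Statistical test results with a reporting floor
#'
#' All tests in the package return an `rts_test` object: the statistic, the
#' effective sample size, the raw two-sided p-value, and a formatting-level
#' floor of 1e-30 below which p is printed as `"<1e-30"` (the raw value is
#' kept).
#'
#' @name rts_test
NULL

P_FLOOR <- 1e-30

new_test_result <- function(statistic_name, statistic, n, p, method,
                            extra = list()) {
  structure(c(list(statistic_name = statistic_name,
                   statistic = unname(statistic), n = n,
                   p = unname(p), p_floor_applied = p < P_FLOOR,
                   method = method), extra),
            class = "rts_test")
}

#' @export
print.rts_test <- function(x, ...) {
  cat(x$method, ": ", x$statistic_name, " = ",
      format(x$statistic, digits = 4), ", n = ", x$n,
      ", p = ", format_p(x$p), "\n", sep = "")
  invisible(x)
}

#' Format a p-value with the 1e-30 reporting floor
#' @param p numeric p-value.
#' @return character; `"<1e-30"` for smaller values.
#' @export
format_p <- function(p) {
  ifelse(p < P_FLOOR, "<1e-30", format(p, digits = 3))
}

#' Spearman's rho from the rank-difference statistic S
#'
#' The no-ties closed form `rho = 1 - 6 S / (n (n^2 - 1))`, where
#' `S = sum d_i^2` over the paired rank differences.
#'
#' @param S sum of squared rank differences (non-negative).
#' @param n number of pairs (>= 2).
#' @return rho.
#' @export
spearman_from_s <- function(S, n) {
  stopifnot(n >= 2, S >= 0)
  1 - 6 * S / (n * (n^2 - 1))
}

# all permutations of 1..n as a matrix (n! x n), lexicographic
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- sub + (sub >= i)
    cbind(rep(i, nrow(m)), m)
  }))
}

# null distribution of S for sample size n: data.frame(S, count)
s_null_distribution <- function(n) {
  P <- all_perms(n)
  S <- rowSums((P - matrix(seq_len(n), nrow(P), n, byrow = TRUE))^2)
  tab <- table(S)
  data.frame(S = as.numeric(names(tab)), count = as.vector(tab))
}

# exact two-sided p for observed S at sample size n: doubled smaller
# S-tail, capped at 1
exact_spearman_p <- function(S_obs, n) {
  d <- s_null_distribution(n)
  total <- sum(d$count)
  lower <- sum(d$count[d$S <= S_obs]) / total
  upper <- sum(d$count[d$S >= S_obs]) / total
  min(1, 2 * min(lower, upper))
}

#' Exact Spearman rank correlation test for small samples
#'
#' For `n <= max_exact` (default 9) and tie-free data, enumerates all `n!`
#' rank permutations, computes the exact null distribution of
#' `S = sum d_i^2`, and reports the two-sided p as twice the smaller
#' S-tail, capped at 1. With ties or larger `n` it falls back to
#' [stats::cor.test()]'s large-sample Spearman test, with a warning in the
#' tie case.
#'
#' @param x,y paired numeric vectors.
#' @param max_exact largest n for full enumeration.
#' @return an [rts_test] with `rho`, plus `S` and `exact` fields.
#' @export
spearman_exact <- function(x, y, max_exact = 9L) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (ties || n > max_exact) {
    if (ties) warning("ties present; using large-sample approximation")
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    return(new_test_result("rho", ct$estimate, n, ct$p.value,
                           "Spearman rank correlation (large-sample)",
                           extra = list(S = unname(ct$statistic), exact = FALSE)))
  }
  rx <- rank(x); ry <- rank(y)
  S <- sum((rx - ry)^2)
  p <- exact_spearman_p(S, n)
  new_test_result("rho", spearman_from_s(S, n), n, p,
                  "Spearman rank correlation (exact enumeration)",
                  extra = list(S = S, exact = TRUE))
}

#' One-sample Wilcoxon signed-rank test on delta-LFE values
#'
#' Wraps [stats::wilcox.test()]. Following the landscape-statistics
#' convention, the values may pool all randomization replicates of each
#' gene; the effective n (`length(values)`) and, when given, the
#' underlying gene count are both recorded so the pseudo-replication is
#' visible.
#'
#' @param values numeric deviations.
#' @param mu null location (default 0).
#' @param n_genes optional number of distinct genes behind `values`.
#' @return an [rts_test] with statistic `V`.
#' @export
wilcoxon_signed <- function(values, mu = 0, n_genes = NULL) {
  nz <- values[values != mu]
  if (length(nz) == 0L) stop("all values equal mu; no nonzero deviations")
  wt <- suppressWarnings(wilcox.test(values, mu = mu))
  new_test_result("V", wt$statistic, length(values), wt$p.value,
                  "Wilcoxon signed-rank test",
                  extra = list(n_genes = n_genes))
}

#' Mann-Whitney U test between two groups of delta-LFE values
#'
#' Wraps [stats::wilcox.test()] (two-sample).
#' @param a,b numeric vectors.
#' @param n_genes optional c(n_a, n_b) distinct gene counts.
#' @return an [rts_test] with statistic `U`.
#' @export
mann_whitney <- function(a, b, n_genes = NULL) {
  wt <- suppressWarnings(wilcox.test(a, b))
  new_test_result("U", wt$statistic, length(a) + length(b), wt$p.value,
                  "Mann-Whitney U test", extra = list(n_genes = n_genes))
}

#' Pearson correlation test
#'
#' Wraps [stats::cor.test()].
#' @param x,y paired numeric vectors.
#' @return an [rts_test] with statistic `r`.
#' @export
pearson <- function(x, y) {
  ct <- cor.test(x, y, method = "pearson")
  new_test_result("r", ct$estimate, length(x), ct$p.value,
                  "Pearson correlation")
}
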