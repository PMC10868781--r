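#' Exact sign-flip permutation test for paired conditions
#'
#' Enumerates all `2^N` sign assignments of per-participant condition
#' differences and compares the observed mean difference with the permuted
#' means. With `M` permuted means strictly greater than the observed one,
#' the one-sided significance level is `(M + 1) / (2^N + 1)`; ties count as
#' not exceeding, which is mildly anti-conservative at the margin. The
#' achievable floor is `1 / (2^N + 1)`.
#'
#' @param x Per-participant values in the first condition, or (when `y` is
#'   NULL) the paired differences directly.
#' @param y Optional per-participant values in the second condition; the
#'   test is one-sided for `mean(x - y) > 0`.
#' @param max_n Largest N enumerated exactly (memory grows as `2^N`).
#' @param n_mc Optional Monte-Carlo sample size used instead of full
#'   enumeration when `N > max_n`; without it, large N is an error so the
#'   fallback is never silent.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return The p-value (scalar).
#' @examples
#' exact_permutation_p(c(1, 1, 1)) # 1/9
#' @export
exact_permutation_p <- function(x, y = NULL, max_n = 20L, n_mc = NULL, seed = 1L) {
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 1, all(is.finite(d)))
  N <- length(d)
  obs <- mean(d)
  if (N > max_n) {
    if (is.null(n_mc)) {
      stop(sprintf(paste0("N = %d exceeds the exact-enumeration limit (%d); ",
                          "pass `n_mc` for a Monte-Carlo approximation"), N, max_n),
           call. = FALSE)
    }
    sums <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_mc * N, replace = TRUE), n_mc, N)
      as.numeric(signs %*% d)
    })
    M <- sum(sums / N > obs)
    return((M + 1) / (n_mc + 1))
  }
  sums <- 0
  for (di in d) sums <- c(sums - di, sums + di)   # all 2^N signed sums
  M <- sum(sums / N > obs)
  (M + 1) / (2^N + 1)
}

#' One-sided unpaired bootstrap exceedance test
#'
#' Tests whether group A's mean exceeds group B's: group A is resampled with
#' replacement `n_boot` times; with `M` resampled means strictly below
#' `mean(groupB)`, the significance level is `(M + 1) / (n_boot + 1)`.
#' Ties count as not exceeding.
#'
#' @param group_a,group_b Numeric vectors (e.g., per-participant coherence in
#'   two experiments).
#' @param n_boot Number of bootstrap resamples (the study used 10,000).
#' @param seed Integer seed.
#' @return The p-value (scalar).
#' @export
bootstrap_unpaired_p <- function(group_a, group_b, n_boot = 10000, seed = 1L) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  n <- length(group_a)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    colMeans(matrix(group_a[idx], n, n_boot))
  })
  M <- sum(means < mean(group_b))
  (M + 1) / (n_boot + 1)
}

#' Bias-corrected and accelerated bootstrap interval for a mean
#'
#' Companion utility to [bootstrap_unpaired_p()]: a BCa confidence interval
#' for the mean of one group (jackknife acceleration, normal-quantile bias
#' correction).
#'
#' @param x Numeric vector.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_bca_ci <- function(x, n_boot = 10000, conf = 0.95, seed = 1L) {
  n <- length(x)
  stopifnot(n >= 2)
  theta <- mean(x)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    colMeans(matrix(x[idx], n, n_boot))
  })
  z0 <- stats::qnorm(mean(boots < theta))
  jack <- (sum(x) - x) / (n - 1)
  jm <- mean(jack)
  a <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
  alpha <- (1 - conf) / 2
  adj <- function(al) {
    z <- z0 + stats::qnorm(al)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  qs <- stats::quantile(boots, probs = c(adj(alpha), adj(1 - alpha)), names = FALSE)
  stats::setNames(qs, c("lower", "upper"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`p * m / rank`, monotonized, capped at 1).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Report table for a set of contrasts
#'
#' Small helper assembling the package's standard statistics table.
#'
#' @param contrast Character labels.
#' @param statistic Observed statistics.
#' @param p_raw Raw p-values.
#' @return A tibble with columns `contrast`, `statistic`, `p_raw`, `p_fdr`.
#' @export
stat_report <- function(contrast, statistic, p_raw) {
  tibble::tibble(contrast = contrast, statistic = statistic,
                 p_raw = p_raw, p_fdr = fdr_adjust(p_raw))
}
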