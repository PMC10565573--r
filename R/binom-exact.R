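#' Exact two-sided binomial p-value against a 1:1 null
#'
#' Computes the exact two-sided p-value for observing `k` successes in `n`
#' Bernoulli(0.5) trials, using the minimum-likelihood convention: the p-value
#' is the total probability of all outcomes whose point mass does not exceed
#' that of the observed outcome. Under the symmetric 0.5 null this reduces to
#' `min(1, 2 * P(X <= min(k, n - k)))`, which is what this function evaluates;
#' it is vectorised over `k` and `n`.
#'
#' This is the test used both for the near-1:1 heterozygosity criterion on DNA
#' allele counts and for the allelic-imbalance test on RNA allele counts.
#'
#' @param k Integer vector, number of alternate-allele reads.
#' @param n Integer vector, number of informative reads (ref + alt).
#' @return Numeric vector of two-sided p-values; `NA` where `n` is 0.
#' @examples
#' binom_p_half(50, 100)  # 1
#' binom_p_half(70, 100)  # ~ 7e-5
#' @export
binom_p_half <- function(k, n) {
  stopifnot(length(k) == length(n) || length(k) == 1L || length(n) == 1L)
  k <- as.numeric(k)
  n <- as.numeric(n)
  if (any(!is.na(k) & !is.na(n) & (k < 0 | k > n))) {
    abort("`k` must lie in [0, n].")
  }
  m <- pmin(k, n - k)
  p <- pmin(1, 2 * pbinom(m, n, 0.5))
  p[n == 0] <- NA_real_
  p
}

#' Clopper-Pearson exact confidence interval for a proportion
#'
#' Exact (central) binomial confidence interval via beta quantiles, vectorised.
#' Used to attach an interval to every per-site RNA allele fraction.
#'
#' @param k Successes (alternate-allele reads).
#' @param n Trials (informative reads).
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with columns `ci_lo`, `ci_hi` (NA where `n` is 0).
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  a <- (1 - conf_level) / 2
  lo <- ifelse(k == 0, 0, qbeta(a, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  lo[n == 0] <- NA_real_
  hi[n == 0] <- NA_real_
  tibble(ci_lo = lo, ci_hi = hi)
}
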