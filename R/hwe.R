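# ---- exact Hardy-Weinberg test --------------------------------------------
#
# Conditional-on-allele-count exact formulation: given n diploid genotypes
# and the minor-allele count m, the heterozygote count h has
#   P(h) = n! / (n_AA! h! n_aa!) * 2^h / C(2n, m)  (normalized over h),
# computed by a log-space recurrence over h (stable to n ~ 1e5). The
# two-sided p-value sums P(h') over all outcomes with P(h') <= P(h_obs).

# distribution and p-values for one (n, minor-count) family; returns a list
# with h (possible het counts), prob, and pval aligned to h
hwe_family_pvalues <- function(n, minor) {
  stopifnot(n >= 1, minor >= 0, minor <= n * 2 - minor)
  h_min <- minor %% 2L
  h <- seq.int(h_min, minor, by = 2L)
  lp <- numeric(length(h))
  if (length(h) > 1) {
    for (i in seq_len(length(h) - 1L)) {
      hh <- h[i]
      na <- (minor - hh) / 2          # minor-allele homozygotes at h = hh
      nb <- n - hh - na               # major-allele homozygotes
      lp[i + 1L] <- lp[i] + log(4 * na * nb) - log((hh + 2) * (hh + 1))
    }
  }
  lp <- lp - max(lp)
  prob <- exp(lp) / sum(exp(lp))
  ord <- order(prob)
  pv <- numeric(length(h))
  pv[ord] <- cumsum(prob[ord])
  # equal-probability outcomes (up to float error) must share a p-value
  tol <- 1e-12
  for (i in order(prob, decreasing = TRUE)) {
    eq <- abs(prob - prob[i]) <= tol * max(prob[i], 1e-300)
    pv[eq] <- max(pv[eq])
  }
  list(h = h, prob = prob, pval = pmin(pv, 1))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability of all heterozygote counts (with the
#' same allele counts) whose probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (vectorized)
#' @return numeric vector of p-values in `(0, 1]`
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  if (any(is.na(c(n_AA, n_Aa, n_aa))) || any(c(n_AA, n_Aa, n_aa) < 0))
    stop("hwe_exact: counts must be nonnegative and non-missing")
  vapply(seq_len(k), function(i) {
    n <- n_AA[i] + n_Aa[i] + n_aa[i]
    if (n == 0) stop("hwe_exact: all-zero genotype counts are undefined")
    nA <- 2 * n_AA[i] + n_Aa[i]
    minor <- min(nA, 2 * n - nA)
    fam <- hwe_family_pvalues(n, minor)
    fam$pval[match(n_Aa[i], fam$h)]
  }, numeric(1))
}
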