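## Group-level aggregation of per-segment posteriors, the two-part
## significance criterion for condition effects, and an exact Wilcoxon
## signed-rank test used by the contribution and lesion analyses.

#' Pool modulator posteriors across segment pairs
#'
#' Group summaries follow the simple-averaging convention: the group mean
#' of a log modulator is the arithmetic mean of per-segment conditional
#' means, and the group 95% interval is the mean of the per-segment 95%
#' interval bounds.  A precision-weighted Bayesian alternative (inverse
#' variance weighting, intervals from the pooled density) is reported
#' alongside when `weighted = TRUE`.
#'
#' @param posteriors list of `bgdcm_posterior`
#' @param weighted also compute the precision-weighted pooling
#' @return data.frame with one row per extrinsic-connection modulator:
#'   group log ratio, averaged CI bounds, implied group posterior mass
#'   above ratio 1, and (optionally) weighted counterparts
#' @export
pool_posteriors <- function(posteriors, weighted = FALSE) {
  if (!length(posteriors)) stopf("no posteriors to pool")
  summ <- lapply(posteriors, modulator_summary)
  conn <- summ[[1]]$connection
  mu <- sapply(summ, `[[`, "log_ratio")      # conn x segments
  sdv <- sapply(summ, `[[`, "sd")
  if (is.null(dim(mu))) { mu <- matrix(mu, nrow = length(conn))
                          sdv <- matrix(sdv, nrow = length(conn)) }
  lo <- mu - 1.96 * sdv; up <- mu + 1.96 * sdv
  out <- data.frame(
    connection = conn,
    log_ratio = rowMeans(mu),
    lo95 = rowMeans(lo),
    up95 = rowMeans(up),
    stringsAsFactors = FALSE
  )
  ## group posterior mass above ratio 1, from the averaged interval treated
  ## as a Gaussian (mean of bounds determines its SD)
  gsd <- (out$up95 - out$lo95) / (2 * 1.96)
  out$p_increase <- pnorm(out$log_ratio / gsd)
  out$ratio <- exp(out$log_ratio)
  if (weighted) {
    w <- 1 / sdv^2
    wmu <- rowSums(mu * w) / rowSums(w)
    wsd <- sqrt(1 / rowSums(w))
    out$w_log_ratio <- wmu
    out$w_lo95 <- wmu - 1.96 * wsd
    out$w_up95 <- wmu + 1.96 * wsd
  }
  out
}

#' Two-part significance criterion for condition effects
#'
#' A connection's OFF/ON gain change is flagged as an increase (or
#' decrease) when (i) the group-pooled posterior places more than
#' `group_mass` of its mass above (below) ratio 1, and (ii) the
#' per-segment 95% interval excludes ratio 1 in the same direction in at
#' least `segment_fraction` of segment pairs (inclusive).  All other
#' connections are `ns`.
#'
#' @param posteriors list of `bgdcm_posterior` (>= 2)
#' @param group_mass group posterior-mass threshold (default 0.95)
#' @param segment_fraction minimum fraction of individually significant
#'   segments (default 0.5, inclusive)
#' @return data.frame per connection: `flag` (`increase`/`decrease`/`ns`),
#'   group ratio and CI, and per-direction segment counts
#' @export
significance_flags <- function(posteriors, group_mass = 0.95,
                               segment_fraction = 0.5) {
  if (length(posteriors) < 2L) stopf("need at least 2 posteriors")
  pooled <- pool_posteriors(posteriors)
  summ <- lapply(posteriors, modulator_summary)
  nseg <- length(summ)
  n_up <- rowSums(sapply(summ, function(s) s$lo95 > 1))
  n_dn <- rowSums(sapply(summ, function(s) s$up95 < 1))
  flag <- rep("ns", nrow(pooled))
  inc <- pooled$p_increase > group_mass & (n_up / nseg >= segment_fraction)
  dec <- (1 - pooled$p_increase) > group_mass & (n_dn / nseg >= segment_fraction)
  flag[inc] <- "increase"
  flag[dec] <- "decrease"
  data.frame(connection = pooled$connection, flag = flag,
             ratio = pooled$ratio, lo95 = exp(pooled$lo95),
             up95 = exp(pooled$up95), p_increase = pooled$p_increase,
             n_segments_up = n_up, n_segments_down = n_dn,
             n_segments = nseg, stringsAsFactors = FALSE)
}

## Exact null distribution of the signed-rank statistic for an arbitrary
## set of (possibly tied, mid-) ranks: dynamic programming over the
## generating function prod_k (1 + x^{2 r_k}) / 2^n on a half-unit grid,
## equivalent to enumerating all 2^n sign assignments.
signed_rank_null_cdf <- function(ranks) {
  u <- as.integer(round(2 * ranks))        # half-unit grid keeps mid-ranks exact
  maxW <- sum(u)
  pmf <- numeric(maxW + 1L); pmf[1L] <- 1
  for (r in u) {
    shifted <- c(numeric(r), pmf[seq_len(maxW + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Two-sided signed-rank test with zero differences dropped and mid-ranks
#' for ties.  For `n <= 25` non-zero differences the p-value is exact,
#' computed from the full null distribution of the statistic over all
#' `2^n` sign assignments (via a generating-function recursion that handles
#' tied ranks); larger samples use the normal approximation with tie
#' correction.
#'
#' @param x,y paired samples, or differences in `x` when `y` is `NULL`
#' @param exact_max largest n for which the exact distribution is used
#' @return list with `statistic` (W, sum of positive ranks), `p_value`,
#'   `n` (non-zero pairs), `method`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) stopf("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    pmf <- signed_rank_null_cdf(r)
    w2 <- as.integer(round(2 * W))
    ## two-sided: double the smaller tail (point mass included once)
    lower <- sum(pmf[seq_len(w2 + 1L)])
    upper <- sum(pmf[(w2 + 1L):length(pmf)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}
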