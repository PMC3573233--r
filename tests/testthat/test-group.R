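## Helpers build light-weight stand-in posteriors: only the modulator
## entries of mean/cov matter for pooling and flagging.
fake_posterior <- function(log_ratios, sds) {
  circ <- std_circuit
  nm <- std_priors$table$name
  mu <- structure(numeric(length(nm)), names = nm)
  sdv <- structure(rep(0.2, length(nm)), names = nm)
  mix <- paste0("m.", names(log_ratios))
  mu[mix] <- log_ratios
  sdv[mix] <- sds
  structure(list(mean = mu, cov = diag(sdv^2), F = 0, trace = 0,
                 converged = TRUE, tau = 1, scale = 1, circuit = "standard"),
            class = "bgdcm_posterior")
}
mods9 <- function(x = 0) structure(rep(x, 9), names = sub(
  "^m\\.", "", grep("^m\\.", std_priors$table$name, value = TRUE)))

test_that("pooling averages conditional means and interval bounds", {
  p1 <- fake_posterior(mods9(0.2), rep(0.1, 9))
  p2 <- fake_posterior(mods9(0.4), rep(0.3, 9))
  pooled <- pool_posteriors(list(p1, p2))
  expect_equal(pooled$log_ratio, rep(0.3, 9))
  expect_equal(pooled$lo95, rep(mean(c(0.2 - 1.96 * 0.1, 0.4 - 1.96 * 0.3)), 9))
  ## single posterior: identity
  single <- pool_posteriors(list(p1))
  expect_equal(single$log_ratio, rep(0.2, 9))
  expect_equal(single$up95, rep(0.2 + 1.96 * 0.1, 9))
  expect_error(pool_posteriors(list()), "no posteriors")
  ## precision-weighted variant present on request
  pw <- pool_posteriors(list(p1, p2), weighted = TRUE)
  wm <- (0.2 / 0.01 + 0.4 / 0.09) / (1 / 0.01 + 1 / 0.09)
  expect_equal(pw$w_log_ratio, rep(wm, 9))
})

test_that("the two-part significance criterion is applied inclusively", {
  ## 12 segments: one connection clearly up in all, one up in exactly 6,
  ## one up in only 5, one strongly down
  lr <- function(ctx_stn, gpe_stn, str_gpe, gpi_thal)
    fake_posterior(c(ctx_stn = ctx_stn, gpe_stn = gpe_stn,
                     str_gpe = str_gpe, gpi_thal = gpi_thal),
                   c(0.05, 0.05, 0.05, 0.05))
  posts <- lapply(1:12, function(i)
    lr(0.4,
       if (i <= 6) 0.4 else 0.02,
       if (i <= 5) 0.4 else 0.02,
       -0.4))
  fl <- significance_flags(posts)
  get <- function(conn) fl$flag[fl$connection == conn]
  expect_equal(get("ctx_stn"), "increase")
  expect_equal(get("gpe_stn"), "increase")   # 6/12 = 50%: inclusive
  expect_equal(get("str_gpe"), "ns")         # 5/12 < 50%
  expect_equal(get("gpi_thal"), "decrease")
  expect_equal(get("stn_gpi"), "ns")
  expect_error(significance_flags(posts[1]), "at least 2")
})

test_that("flag criterion is antisymmetric under inverting all ratios", {
  set.seed(5)
  posts <- lapply(1:8, function(i)
    fake_posterior(mods9(0) + rnorm(9, c(0.3, -0.3, rep(0, 7)), 0.02),
                   rep(0.05, 9)))
  flipped <- lapply(posts, function(p) { p$mean <- -p$mean; p })
  f1 <- significance_flags(posts)
  f2 <- significance_flags(flipped)
  swap <- c(increase = "decrease", decrease = "increase", ns = "ns")
  expect_equal(unname(swap[f1$flag]), f2$flag)
})

test_that("exact Wilcoxon p equals full sign-flip enumeration", {
  set.seed(13)
  d <- c(0.8, -0.2, 1.4, 0.5, -0.9, 0.3, 2.2, -0.4, 0.6, 1.1, -1.3, 0.25)
  res <- wilcoxon_signed_rank(d)
  ## brute force over all 2^12 sign assignments
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 12)))
  Wnull <- signs %*% r
  mu <- sum(r) / 2
  p_exact <- min(1, 2 * min(mean(Wnull <= W_obs), mean(Wnull >= W_obs)))
  expect_equal(res$statistic, W_obs)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("exact Wilcoxon handles ties and zeros and matches base R when exact", {
  d <- c(1, -1, 2, 2, -3, 4, 0, 5, -2)      # zeros dropped, mid-ranks
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$n, 8L)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  ## no ties: agrees with base R's exact test
  set.seed(17)
  x <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x)$p_value,
               suppressWarnings(wilcox.test(x, exact = TRUE)$p.value),
               tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
})

test_that("Wilcoxon p is invariant to pair order and monotone rescaling", {
  set.seed(19)
  d <- rnorm(12)
  p0 <- wilcoxon_signed_rank(d)$p_value
  expect_equal(wilcoxon_signed_rank(sample(d))$p_value, p0)
  ## strictly monotone transform of |d| preserving signs preserves ranks
  d2 <- sign(d) * (abs(d)^3 + abs(d))
  expect_equal(wilcoxon_signed_rank(d2)$p_value, p0)
})

test_that("Wilcoxon type-I error is controlled at the nominal level", {
  set.seed(23)
  reps <- 10000
  rej <- 0L
  for (i in seq_len(reps)) {
    d <- rnorm(12)
    if (wilcoxon_signed_rank(d)$p_value < 0.01) rej <- rej + 1L
  }
  rate <- rej / reps
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.02)
})

test_that("conditional correlation summaries behave on closed forms", {
  V <- matrix(c(4, 2, 2, 4), 2)
  cc <- conditional_correlations(V, indices = 1:2)
  expect_equal(cc$correlation[1, 2], 0.5)
  expect_equal(diag(cc$correlation), c(1, 1))
  Vd <- diag(c(1, 2, 3))
  cc2 <- conditional_correlations(Vd, indices = 1:3)
  expect_equal(cc2$mean_abs, 0)
  expect_error(conditional_correlations(diag(c(1, 0)), indices = 1:2),
               "zero-variance")
})
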