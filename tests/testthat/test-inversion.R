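test_that("free energy reduces to accuracy when posterior equals prior", {
  set.seed(3)
  resid <- rnorm(20)
  mu <- c(0.3, -0.2)
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  F1 <- free_energy(resid, tau = 2, J = NULL, post_mean = mu, post_cov = V,
                    prior_mean = mu, prior_cov = V)
  n <- length(resid)
  acc <- -0.5 * 2 * sum(resid^2) + 0.5 * n * log(2) - 0.5 * n * log(2 * pi)
  expect_equal(F1, acc)                    # complexity exactly zero
})

test_that("free energy matches a hand-computed two-parameter oracle", {
  ## independent implementation of the Laplace formula
  set.seed(4)
  resid <- rnorm(15)
  tau <- 1.7
  J <- matrix(rnorm(30), 15, 2)
  mu_q <- c(0.2, -0.1); V_q <- matrix(c(0.05, 0.01, 0.01, 0.02), 2)
  mu_0 <- c(0, 0); V_0 <- diag(0.25, 2)
  n <- 15
  kl <- 0.5 * (sum(diag(solve(V_0) %*% V_q)) +
                 t(mu_q - mu_0) %*% solve(V_0) %*% (mu_q - mu_0) - 2 +
                 log(det(V_0) / det(V_q)))
  Fref <- -0.5 * tau * sum(resid^2) + 0.5 * n * log(tau) -
    0.5 * n * log(2 * pi) - 0.5 * tau * sum(diag(J %*% V_q %*% t(J))) -
    drop(kl)
  expect_equal(free_energy(resid, tau, J, mu_q, V_q, mu_0, V_0), Fref,
               tolerance = 1e-8)
})

test_that("widening the prior at a fixed fit lowers the complexity penalty", {
  ## fixed data fit (residual, precision, Jacobian, posterior mean); the
  ## posterior covariance is the Laplace one implied by each prior, so
  ## widening the prior relaxes the complexity penalty
  set.seed(6)
  resid <- rep(0.5, 10)
  tau <- 2
  J <- matrix(rnorm(20), 10, 2)
  mu_q <- c(0.3, 0.3)
  F_of <- function(prior_sd) {
    V0 <- diag(prior_sd^2, 2)
    Vq <- solve(tau * crossprod(J) + solve(V0))
    F_val <- free_energy(resid, tau, J, mu_q, Vq, c(0, 0), V0)
    acc <- -0.5 * tau * sum(resid^2) + 0.5 * 10 * log(tau) -
      0.5 * 10 * log(2 * pi) - 0.5 * tau * sum(diag(J %*% Vq %*% t(J)))
    acc - F_val                           # = complexity (KL)
  }
  ## monotone where the mean-displacement penalty dominates (tight priors)
  kl <- vapply(c(0.1, 0.2, 0.3), F_of, 0)
  expect_true(all(diff(kl) < 0))
  expect_true(all(kl > 0))                # KL is non-negative
})

test_that("free energy never exceeds the MAP log-likelihood", {
  ## F = accuracy - KL <= accuracy <= log-likelihood at the MAP
  set.seed(9)
  for (k in 1:5) {
    resid <- rnorm(12); tau <- runif(1, 0.5, 5)
    J <- matrix(rnorm(36), 12, 3)
    mu <- rnorm(3, 0, 0.3)
    V0 <- diag(runif(3, 0.05, 0.5))
    Vq <- solve(tau * crossprod(J) + solve(V0))
    loglik <- -0.5 * tau * sum(resid^2) + 0.5 * 12 * log(tau) -
      0.5 * 12 * log(2 * pi)
    expect_lte(free_energy(resid, tau, J, mu, Vq, rep(0, 3), V0), loglik)
  }
})

test_that("Bayes factor identities hold", {
  expect_equal(bayes_factor(3, 3), 1)
  expect_equal(posterior_model_probability(1), 0.5)
  expect_equal(bayes_factor(log(150), 0), 150, tolerance = 1e-12)
  expect_gt(posterior_model_probability(150), 0.99)
  expect_equal(posterior_model_probability(150), 150 / 151)
})

test_that("fixed-effects pooling sums per-segment evidence order-invariantly", {
  Fm <- list(a = c(1, 2, 3), b = c(4, 0, 2.5))
  pooled <- fixed_effects_pool(Fm)
  expect_equal(as.numeric(pooled), c(6, 6.5))
  expect_equal(attr(pooled, "ranking")[1], "b")
  perm <- list(a = Fm$a[c(3, 1, 2)], b = Fm$b[c(3, 1, 2)])
  expect_equal(as.numeric(fixed_effects_pool(perm)), as.numeric(pooled))
  expect_error(fixed_effects_pool(list(a = 1:3, b = 1:2)), "same segment")
  ## two segments with dF = 3 each pool to dF = 6
  p2 <- fixed_effects_pool(list(m1 = c(10, 20), m2 = c(7, 17)))
  expect_equal(unname(p2["m1"] - p2["m2"]), 6)
})

test_that("fit screening excludes robust outliers only", {
  mk <- function(F) structure(list(F = F), class = "bgdcm_posterior")
  same <- lapply(rep(5, 6), mk)
  expect_length(screen_fits(same)$excluded, 0)
  Fs <- c(100, 101, 99, 100.5, 99.5, 100 - 10 * mad(c(100, 101, 99, 100.5, 99.5, 60)))
  posts <- lapply(c(100, 101, 99, 100.5, 99.5, 60), mk)
  scr <- screen_fits(posts)
  expect_equal(scr$excluded, 6L)
  expect_equal(scr$kept, 1:5)
  expect_error(screen_fits(list()), "no posteriors")
})

test_that("inversion recovers the truth from noiseless operator-consistent features", {
  circ <- std_circuit
  th <- default_theta(circ)
  th$mods[c("ctx_stn", "gpe_stn", "stn_gpi")] <- 1.5
  fs_d <- 125
  fgrid <- seq(0, fs_d / 2, by = 0.5)
  H2 <- decimation_filter_gain(8L, fgrid, 1000)
  op_data <- function(cond) {
    full <- predict_csd(circ, th, fgrid, cond)
    full$S <- full$S * H2
    out <- csd_var_reduce(full, 8L, fs_d, 13:35)
    out$fs <- fs_d; out$var_order <- 8L
    out$decimation <- list(factor = 8L, fs_raw = 1000)
    out
  }
  post <- invert_pair(circ, std_priors, op_data("off"), op_data("on"),
                      control = list(max_iter = 48L))
  s <- modulator_summary(post)
  truth_up <- s$connection %in% c("ctx_stn", "gpe_stn", "stn_gpi")
  expect_true(all(abs(s$ratio[truth_up] - 1.5) < 0.05))
  expect_true(all(abs(s$ratio[!truth_up] - 1) < 0.05))
  ## free-energy trace non-decreasing over accepted iterations
  expect_true(all(diff(post$trace) > -1e-6))
  ## conditional correlations are modest (identifiable parameterisation)
  expect_lt(conditional_correlations(post)$mean_abs, 0.5)
})

test_that("truth at the prior mean yields modulators covering one", {
  circ <- std_circuit
  csd_on <- predict_csd(circ, default_theta(circ), 13:35, "on")
  csd_off <- predict_csd(circ, default_theta(circ), 13:35, "off")
  post <- invert_pair(circ, std_priors, csd_off, csd_on,
                      control = list(max_iter = 16L))
  s <- modulator_summary(post)
  expect_true(all(s$lo95 <= 1 & s$up95 >= 1))
})

test_that("posterior containers round trip through JSON", {
  mk <- structure(list(mean = c(a = 0.1, b = -0.2),
                       cov = matrix(c(0.04, 0.01, 0.01, 0.02), 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))),
                       F = -12.5, trace = c(-20, -12.5), converged = TRUE,
                       tau = 3.2, scale = 1.1, circuit = "standard",
                       n_features = 414), class = "bgdcm_posterior")
  path <- withr::local_tempfile(fileext = ".json")
  write_posterior(mk, path)
  back <- read_posterior(path)
  expect_equal(back$mean, mk$mean)
  expect_equal(back$cov, mk$cov)
  expect_equal(back$F, mk$F)
})
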