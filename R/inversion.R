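## Variational Laplace inversion of the spectral forward model.  A paired
## OFF/ON segment is fitted jointly: all parameters are shared across the
## two conditions except the condition modulators (OFF/ON log gain ratios)
## of the extrinsic connections.  Real and imaginary parts of the
## upper-triangle cross-spectral entries are treated as independent
## Gaussian features whose precision is a hyperparameter updated inside
## the optimisation; parameters are Gauss-Newton updated with
## Levenberg-Marquardt regularisation and step rejection whenever the free
## energy decreases.

#' Prior density over the estimable parameters
#'
#' Builds the Gaussian prior over the log-deviation parameter vector: zero
#' mean (the prior-mean parameterisation of [default_theta()]) and a
#' diagonal covariance with per-block standard deviations from the priors
#' configuration (connection gains, condition modulators, observation
#' gains, noise parameters, synaptic rate constants).
#'
#' @param circuit a `bgdcm_circuit`
#' @param cfg parsed priors configuration
#' @return object of class `bgdcm_priors`: list with `mean`, `cov`,
#'   `table` (parameter names and blocks), `theta0`
#' @export
default_priors <- function(circuit, cfg = load_priors_config()) {
  tab <- theta_param_table(circuit, cfg)
  mu <- structure(numeric(nrow(tab)), names = tab$name)
  structure(list(mean = mu, cov = diag(tab$sd^2), table = tab,
                 theta0 = default_theta(circuit, cfg)),
            class = "bgdcm_priors")
}

## Real feature vector of one CSD: per frequency the channel auto-spectra
## followed by Re and Im of each upper-triangle cross-spectrum.
csd_features <- function(csd) {
  nch <- length(csd$labels)
  ut <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  feats <- lapply(seq_along(csd$freqs), function(i) {
    M <- csd$S[i, , ]
    c(Re(diag(M)), Re(M[ut]), Im(M[ut]))
  })
  unlist(feats)
}

## Gaussian Laplace free energy: accuracy - complexity.
#' Variational (Laplace) free energy of a fitted model
#'
#' `F = -tau/2 r'r + n/2 log(tau) - n/2 log(2 pi) - tau/2 tr(J Sq J') -
#' KL(q || prior)`, where `r` is the feature residual, `tau` the feature
#' precision, `J` the prediction Jacobian at the posterior mean and the KL
#' term (the complexity) is the Gaussian Kullback-Leibler divergence from
#' the posterior `q` to the prior.  The complexity is zero exactly when
#' posterior and prior coincide.
#'
#' @param resid residual vector (data minus prediction at the posterior
#'   mean)
#' @param tau feature noise precision: a scalar, or a vector with one
#'   precision per residual entry (block-wise precision components)
#' @param J Jacobian of the prediction w.r.t. the parameters (n x np); may
#'   be `NULL` to omit the curvature penalty
#' @param post_mean,post_cov posterior mean and covariance
#' @param prior_mean,prior_cov prior mean and covariance
#' @return scalar free energy (nats)
#' @export
free_energy <- function(resid, tau, J, post_mean, post_cov,
                        prior_mean, prior_cov) {
  n <- length(resid)
  if (length(tau) == 1L) tau <- rep(tau, n)
  if (length(tau) != n) stopf("tau must be scalar or match the residual")
  np <- length(post_mean)
  if (length(prior_mean) != np) stopf("prior/posterior dimension mismatch")
  cp <- chol(prior_cov)            # errors on non-PD prior
  cq <- chol(post_cov)
  P0 <- chol2inv(cp)
  dm <- post_mean - prior_mean
  kl <- 0.5 * (sum(diag(P0 %*% post_cov)) + drop(t(dm) %*% P0 %*% dm) - np +
                 2 * sum(log(diag(cp))) - 2 * sum(log(diag(cq))))
  curv <- if (is.null(J)) 0 else
    0.5 * sum(tau * rowSums((J %*% post_cov) * J))
  acc <- -0.5 * sum(tau * resid^2) + 0.5 * sum(log(tau)) -
    0.5 * n * log(2 * pi) - curv
  acc - kl
}

#' Invert a paired OFF/ON cross-spectral data set
#'
#' Fits the circuit's spectral forward model jointly to an OFF and an ON
#' cross-spectral density by Gauss-Newton/Levenberg-Marquardt ascent on the
#' variational free energy over log-parameters.  Only the condition
#' modulators differ between conditions.  The overall data scale (which is
#' arbitrary, recording gains being unknown) is matched to the prior-mean
#' prediction before fitting and recorded in the result.
#'
#' @param circuit a `bgdcm_circuit`
#' @param priors a `bgdcm_priors`
#' @param csd_off,csd_on `bgdcm_csd` objects on a common grid and labels
#' @param control list of optimiser settings: `max_iter` (128), `tol`
#'   (1e-2 nats), `tol_steps` (3 successive accepted small improvements),
#'   `fd_step` (Jacobian finite-difference step, 1e-3), `operator`
#'   (`"var"`: reduce predictions through the same VAR model order as the
#'   data features, the default when the features carry their VAR
#'   provenance; `"direct"`: compare raw model spectra), `verbose`
#' @return object of class `bgdcm_posterior`: `mean` and `cov` of the
#'   log-parameter posterior, free energy `F`, iteration `trace`,
#'   `converged`, feature precision `tau`, data `scale`, and `circuit`
#'   name
#' @export
invert_pair <- function(circuit, priors, csd_off, csd_on, control = list()) {
  ctl <- modifyList(list(max_iter = 128L, tol = 1e-2, tol_steps = 3L,
                         fd_step = 1e-3, verbose = FALSE,
                         operator = NULL, init = NULL, gamma_init = 1 / 64,
                         gamma_min = 1 / 512), control)
  if (!isTRUE(all.equal(csd_off$freqs, csd_on$freqs)) ||
      !identical(csd_off$labels, csd_on$labels))
    stopf("OFF and ON features must share frequency grid and labels")
  freqs <- csd_off$freqs
  theta0 <- priors$theta0
  nm <- priors$table$name
  np <- length(nm)
  is_mod <- priors$table$block == "mod"

  ## operator-consistent prediction: when the data features came from a
  ## VAR reduction, predictions are passed through the same model-order
  ## reduction (population Yule-Walker at the decimated rate)
  operator <- ctl$operator %||%
    (if (!is.null(csd_off$fs) && !is.null(csd_off$var_order)) "var"
     else "direct")
  if (operator == "var") {
    fs_d <- csd_off$fs
    p_var <- csd_off$var_order
    fgrid <- seq(0, fs_d / 2, by = 1)
    ## the anti-alias filter shapes what the data VAR sees; apply its exact
    ## response to the prediction before the model-order reduction
    H2 <- if (!is.null(csd_off$decimation))
      decimation_filter_gain(csd_off$decimation$factor, fgrid,
                             csd_off$decimation$fs_raw)
    else rep(1, length(fgrid))
    predict_one <- function(th, cond) {
      full <- predict_csd(circuit, th, fgrid, cond)
      full$S <- full$S * H2                # recycles over freq (first) index
      csd_features(csd_var_reduce(full, p_var, fs_d, freqs))
    }
  } else {
    predict_one <- function(th, cond)
      csd_features(predict_csd(circuit, th, freqs, cond))
  }

  h_fun <- function(p, part = c("both", "off", "on")) {
    part <- match.arg(part)
    th <- apply_param_vector(theta0, structure(p, names = nm), circuit)
    if (part == "off") return(predict_one(th, "off"))
    if (part == "on") return(predict_one(th, "on"))
    c(predict_one(th, "off"), predict_one(th, "on"))
  }

  ## scale data to the prior-mean prediction (overall scale is nuisance)
  p0 <- numeric(np)
  h0 <- tryCatch(h_fun(p0), error = function(e)
    stopf("prior-mean prediction failed: %s", conditionMessage(e)))
  y_raw <- c(csd_features(csd_off), csd_features(csd_on))
  n <- length(y_raw)
  nh <- n %/% 2L
  nch <- length(csd_off$labels)
  blk <- nh %/% length(freqs)              # features per frequency
  auto_ix <- which(((seq_len(n) - 1L) %% blk) < nch)
  scale <- mean(h0[auto_ix]) / mean(y_raw[auto_ix])
  y_sc <- y_raw * scale

  ## per-channel-pair weights: every feature series is normalised by the
  ## geometric mean of the two channels' band-average auto power, so all
  ## channels inform the (single-precision) Gaussian likelihood equally
  ## rather than the strongest spectrum dominating the residual
  pos <- (seq_len(nh) - 1L) %% blk + 1L
  Pbar <- vapply(seq_len(nch), function(i)
    mean(y_sc[c(which(pos == i), nh + which(pos == i))]), 0)
  Pbar <- pmax(Pbar, 1e-12)
  ut <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  wblk <- c(1 / Pbar, rep(1 / sqrt(Pbar[ut[, 1]] * Pbar[ut[, 2]]), 2))
  w <- rep(rep(wblk, length(freqs)), 2)
  y <- y_sc * w
  h_raw <- h_fun
  h_fun <- function(p, part = c("both", "off", "on")) {
    part <- match.arg(part)
    hv <- h_raw(p, part)
    if (part == "both") hv * w else if (part == "off") hv * w[seq_len(nh)]
    else hv * w[(nh + 1):n]
  }
  h0 <- h0 * w

  P0inv <- chol2inv(chol(priors$cov))
  jac <- function(p, h) {
    J <- matrix(0, n, np)
    for (i in seq_len(np)) {
      dp <- p; dp[i] <- dp[i] + ctl$fd_step
      hi <- if (is_mod[i]) c(h_fun(dp, "off"), h[(nh + 1):n]) else h_fun(dp)
      J[, i] <- (hi - h) / ctl$fd_step
    }
    J
  }

  ## feature-noise precision: a single shared hyperparameter by default
  ## (stable joint ascent); optionally one component per channel pair
  ## (autos and the Re/Im of each cross share a component), both updated by
  ## damped fixed point inside the variational loop
  pair_of_block <- if (isTRUE(ctl$precision_blocks))
    c(seq_len(nch), nch + seq_len(nrow(ut)), nch + seq_len(nrow(ut)))
  else rep(1L, nch + 2L * nrow(ut))
  gidx <- rep(rep(pair_of_block, length(freqs)), 2)
  ngroups <- max(gidx)
  n_g <- tabulate(gidx, ngroups)
  tau_cap <- 1e10        # keeps a perfect (noise-free) fit finite
  ## likelihood tempering: VAR-derived features are smooth functions of the
  ## underlying autoregressive parameters, so the band grid oversamples the
  ## information they carry; the precision is scaled by the ratio of
  ## independent quantities (VAR coefficients + innovation covariance, both
  ## conditions) to the number of features, keeping posterior credible
  ## intervals calibrated
  temper <- ctl$temper %||% if (operator == "var") {
    p_var <- csd_off$var_order
    min(1, 2 * (nch^2 * p_var + nch * (nch + 1) / 2) / n)
  } else 1
  tau_vec <- function(tau_g) tau_g[gidx]
  post_cov_of <- function(tau_g, J)
    chol2inv(chol(crossprod(J, J * tau_vec(tau_g)) + P0inv))
  tau_update <- function(r, J, tau_g) {
    for (k in 1:4) {
      Sq <- post_cov_of(tau_g, J)
      tr_i <- rowSums((J %*% Sq) * J)
      ss <- vapply(seq_len(ngroups), function(g) {
        ix <- gidx == g
        sum(r[ix]^2) + sum(tr_i[ix])
      }, 0)
      target <- pmin(temper * n_g / pmax(ss, n_g / tau_cap), tau_cap)
      ## damped log-space step keeps the joint ascent stable
      tau_g <- exp(log(tau_g) + pmin(pmax(log(target / tau_g), -4), 4) / 2)
    }
    tau_g
  }

  p <- if (is.null(ctl$init)) p0 else unname(ctl$init[nm])
  h <- if (is.null(ctl$init)) h0 else h_fun(p)
  r <- y - h
  tau_g <- rep(min(n / max(sum(r^2), n / tau_cap), tau_cap), ngroups)
  J <- jac(p, h)
  tau_g <- tau_update(r, J, tau_g)
  Sq <- post_cov_of(tau_g, J)
  Fcur <- free_energy(r, tau_vec(tau_g), J, p, Sq, priors$mean, priors$cov)
  trace <- Fcur
  gamma <- ctl$gamma_init
  small <- 0L
  converged <- FALSE
  fail <- 0L

  for (it in seq_len(ctl$max_iter)) {
    Pi <- tau_vec(tau_g)
    H <- crossprod(J, J * Pi) + P0inv
    g <- drop(crossprod(J, Pi * r)) - drop(P0inv %*% p)
    accepted <- FALSE
    for (try in 1:8) {
      dp <- tryCatch(solve(H + diag(gamma * diag(H), np), g),
                     error = function(e) NULL)
      if (!is.null(dp)) {
        p_new <- p + dp
        h_new <- tryCatch(h_fun(p_new), error = function(e) NULL)
        if (!is.null(h_new) && all(is.finite(h_new))) {
          r_new <- y - h_new
          F_new <- free_energy(r_new, Pi, J, p_new, Sq,
                               priors$mean, priors$cov)
          if (is.finite(F_new) && F_new > Fcur - 1e-9) {
            accepted <- TRUE
            break
          }
        }
      }
      gamma <- gamma * 8
    }
    if (!accepted) {
      fail <- fail + 1L
      if (fail >= 2L) break
      gamma <- 1
      next
    }
    gamma <- max(gamma / 8, ctl$gamma_min)
    dF <- F_new - Fcur
    p <- p_new; h <- h_new; r <- r_new
    J <- jac(p, h)
    tau_g <- tau_update(r, J, tau_g)
    Sq <- post_cov_of(tau_g, J)
    Fcur <- free_energy(r, tau_vec(tau_g), J, p, Sq, priors$mean, priors$cov)
    trace <- c(trace, Fcur)
    if (ctl$verbose)
      message(sprintf("  iter %3d  F = %.3f  dF = %.4f", it, Fcur, dF))
    small <- if (abs(dF) < ctl$tol) small + 1L else 0L
    if (small >= ctl$tol_steps) { converged <- TRUE; break }
  }

  names(p) <- nm
  dimnames(Sq) <- list(nm, nm)
  structure(list(mean = p, cov = Sq, F = Fcur, trace = trace,
                 converged = converged, tau = tau_g, scale = scale,
                 circuit = circuit$name, n_features = n),
            class = "bgdcm_posterior")
}

#' @export
print.bgdcm_posterior <- function(x, ...) {
  cat(sprintf("<bgdcm_posterior> circuit '%s': F = %.2f, %d accepted iterations%s\n",
              x$circuit, x$F, length(x$trace) - 1L,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Summary of condition modulators from one posterior
#'
#' Per extrinsic connection: posterior mean and SD of the log OFF/ON gain
#' ratio, the ratio itself, its 95% interval, and the posterior mass above
#' ratio 1.
#'
#' @param posterior a `bgdcm_posterior`
#' @return data.frame, one row per modulator
#' @export
modulator_summary <- function(posterior) {
  ix <- grep("^m\\.", names(posterior$mean))
  mu <- posterior$mean[ix]
  sdv <- sqrt(diag(posterior$cov)[ix])
  data.frame(connection = sub("^m\\.", "", names(mu)),
             log_ratio = unname(mu), sd = unname(sdv),
             ratio = unname(exp(mu)),
             lo95 = unname(exp(mu - 1.96 * sdv)),
             up95 = unname(exp(mu + 1.96 * sdv)),
             p_increase = unname(pnorm(mu / sdv)),
             stringsAsFactors = FALSE)
}

#' Natural-scale parameter set at a posterior mean
#'
#' Applies a posterior's log-parameter deviations to the prior-mean
#' parameter set, returning the MAP `bgdcm_theta` (gains, modulators,
#' observation and noise parameters on their natural scales) for use in
#' the contribution and lesion analyses.
#'
#' @param posterior a `bgdcm_posterior`
#' @param circuit the circuit it was fitted with
#' @param priors the priors it was fitted with
#' @return a `bgdcm_theta`
#' @export
posterior_theta <- function(posterior, circuit = build_standard_circuit(),
                            priors = default_priors(circuit)) {
  apply_param_vector(priors$theta0, posterior$mean, circuit)
}

#' Bayes factor and posterior model probability
#'
#' `BF = exp(F1 - F2)`; under equal model priors the posterior probability
#' of model 1 is `BF / (1 + BF)`.
#'
#' @param F1,F2 free energies (log evidences) of the two models
#' @return scalar Bayes factor
#' @export
bayes_factor <- function(F1, F2) exp(F1 - F2)

#' @rdname bayes_factor
#' @param BF a Bayes factor
#' @export
posterior_model_probability <- function(BF) BF / (1 + BF)

#' Fixed-effects pooling of model evidence
#'
#' Sums free energies over segment pairs for each candidate model.  All
#' models must have been fitted to the same segment set.
#'
#' @param F_list named list (one entry per model) of equal-length numeric
#'   vectors of per-segment free energies, or a segments x models matrix
#' @return named numeric vector of group log evidences, with attribute
#'   `ranking` (model names, best first)
#' @export
fixed_effects_pool <- function(F_list) {
  if (is.matrix(F_list)) F_list <- as.list(as.data.frame(F_list))
  lens <- lengths(F_list)
  if (length(unique(lens)) != 1L)
    stopf("all models must be fitted to the same segment set")
  out <- vapply(F_list, sum, 0)
  attr(out, "ranking") <- names(sort(out, decreasing = TRUE))
  out
}

#' Screen out poorly fitting segment pairs
#'
#' Robust exclusion rule: a pair is excluded when its free energy falls
#' more than `k` median absolute deviations (scaled, consistent with a
#' normal SD) below the cohort median.
#'
#' @param posteriors list of `bgdcm_posterior`
#' @param k MAD multiplier (default 3)
#' @return list with `kept`, `excluded` (integer indices) and the
#'   screened `posteriors`
#' @export
screen_fits <- function(posteriors, k = 3) {
  if (!length(posteriors)) stopf("no posteriors to screen")
  Fv <- vapply(posteriors, `[[`, 0, "F")
  m <- median(Fv); s <- mad(Fv)
  bad <- if (s > 0) which(Fv < m - k * s) else integer(0)
  if (length(bad) == length(Fv)) stopf("all segment pairs excluded")
  list(kept = setdiff(seq_along(Fv), bad), excluded = bad,
       posteriors = posteriors[setdiff(seq_along(Fv), bad)])
}

#' Conditional correlations among condition modulators
#'
#' Off-diagonal posterior correlations among the extrinsic-connection
#' modulators, summarised as mean +/- SEM of their absolute values — a
#' diagnostic for identifiability (large values mean two modulators could
#' explain the same data feature).
#'
#' @param posterior a `bgdcm_posterior`, or a covariance matrix
#' @param indices columns to use when a bare covariance is given (default:
#'   modulator entries for a posterior)
#' @return list with `correlation` matrix, `mean_abs`, `sem_abs`
#' @export
conditional_correlations <- function(posterior, indices = NULL) {
  V <- if (inherits(posterior, "bgdcm_posterior")) posterior$cov else posterior
  if (is.null(indices))
    indices <- if (inherits(posterior, "bgdcm_posterior"))
      grep("^m\\.", colnames(V)) else seq_len(ncol(V))
  V <- V[indices, indices, drop = FALSE]
  if (any(diag(V) <= 0)) stopf("zero-variance entry in covariance")
  R <- cov2cor(V)
  off <- abs(R[upper.tri(R)])
  list(correlation = R, mean_abs = mean(off),
       sem_abs = sd(off) / sqrt(length(off)))
}

#' @importFrom stats cov2cor
NULL

#' Write / read a posterior container (JSON)
#'
#' @param posterior a `bgdcm_posterior`
#' @param path file path
#' @return `read_posterior` returns a `bgdcm_posterior`
#' @export
write_posterior <- function(posterior, path) {
  obj <- unclass(posterior)
  obj$mean <- as.list(obj$mean)              # keep names through JSON
  obj$cov <- unname(obj$cov)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stopf("incompatible posterior file version")
  obj$format_version <- NULL
  obj$mean <- unlist(obj$mean)
  nm <- names(obj$mean)
  obj$cov <- matrix(as.numeric(obj$cov), length(nm), length(nm),
                    dimnames = list(nm, nm))
  structure(obj, class = "bgdcm_posterior")
}
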