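## Ground-truth cohort generation.  Emulates the study layout the pipeline
## is designed for: five subjects, three ~50 s segment pairs per drug
## condition, one bipolar scalp EEG channel over motor cortex and three
## bipolar deep contacts per deep site (STN, GPi), sampled at 1 kHz.  The
## OFF condition strengthens a known set of extrinsic connections by a
## known ratio, giving every downstream stage a recoverable ground truth.

## Real series of length n at rate fs whose two-sided PSD is
## a_white + a_pink / max(f, 1)  (spectral synthesis).
synth_noise_series <- function(n, fs, a_white, a_pink) {
  f <- seq(0, fs / 2, by = fs / n)
  S <- a_white + a_pink / pmax(f, 1)
  nf <- length(f)
  amp <- sqrt(n * fs * S / 2)
  re <- rnorm(nf); im <- rnorm(nf)
  X <- complex(real = amp * re, imaginary = amp * im)
  X[1] <- sqrt(2) * amp[1] * re[1]                    # DC real
  if (n %% 2 == 0) X[nf] <- sqrt(2) * amp[nf] * re[nf] # Nyquist real
  full <- c(X, Conj(rev(X[2:(nf - 1L + n %% 2)])))
  Re(fft(full, inverse = TRUE)) / n
}

cohort_format_version <- 1L

#' Generate a ground-truth cohort of paired condition parameter sets
#'
#' For each subject a base parameter set is drawn around the prior mean
#' (log-normal jitter on the extrinsic gains, SD `subject_sd`); the OFF
#' condition multiplies the gains named in `off_ratios` by their ratios.
#' Each segment pair applies a further small log-normal jitter
#' (`segment_sd`) shared between its OFF and ON members, so the OFF/ON
#' ratio is exact ground truth for every pair.  Parameterisations whose
#' OFF or ON linearisation is unstable are redrawn (up to `max_redraw`).
#' All per-segment simulation seeds are drawn here and recorded, so a
#' cohort is bit-identical under the same seed.
#'
#' @param n_subjects number of subjects (default 5)
#' @param segments_per_condition paired segments per subject (default 3)
#' @param off_ratios named vector of OFF/ON gain ratios; the default
#'   strengthens the hyperdirect (ctx_stn), pallido-subthalamic (gpe_stn)
#'   and subthalamo-pallidal (stn_gpi) connections by 1.5 in the OFF state
#' @param seed integer master seed
#' @param subject_sd,segment_sd log-normal jitter SDs (log units)
#' @param max_redraw redraw cap for unstable draws
#' @return object of class `bgdcm_cohort`
#' @export
make_ground_truth <- function(n_subjects = 5L, segments_per_condition = 3L,
                              off_ratios = c(ctx_stn = 1.5, gpe_stn = 1.5,
                                             stn_gpi = 1.5),
                              seed = 1L, subject_sd = 0.1, segment_sd = 0.05,
                              max_redraw = 10L) {
  if (any(off_ratios <= 0)) stopf("off_ratios must be positive")
  circuit <- build_standard_circuit()
  if (length(setdiff(names(off_ratios), extrinsic_ids(circuit))))
    stopf("off_ratios name unknown connections")
  theta0 <- default_theta(circuit)
  ext <- extrinsic_ids(circuit)
  set.seed(seed)

  stable <- function(th) {
    ss <- linearize(circuit, th)
    ss$stable
  }
  jittered <- function(base, sdv) {
    for (k in seq_len(max_redraw)) {
      th <- base
      th$gains[ext] <- base$gains[ext] * exp(rnorm(length(ext), 0, sdv))
      off <- th
      off$gains[names(off_ratios)] <- off$gains[names(off_ratios)] * off_ratios
      if (stable(th) && stable(off)) return(list(on = th, off = off))
    }
    stopf("could not draw a stable parameter set in %d attempts", max_redraw)
  }

  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    base <- jittered(theta0, subject_sd)
    segs <- vector("list", segments_per_condition)
    for (g in seq_len(segments_per_condition)) {
      pair <- jittered(base$on, segment_sd)
      segs[[g]] <- list(theta_on = pair$on, theta_off = pair$off,
                        seed_on = sample.int(.Machine$integer.max, 1L),
                        seed_off = sample.int(.Machine$integer.max, 1L))
    }
    subjects[[s]] <- list(id = s, segments = segs)
  }
  structure(list(format_version = cohort_format_version,
                 circuit = "standard", off_ratios = off_ratios,
                 seed = seed, subject_sd = subject_sd,
                 segment_sd = segment_sd, subjects = subjects),
            class = "bgdcm_cohort")
}

#' @export
print.bgdcm_cohort <- function(x, ...) {
  nseg <- length(x$subjects[[1]]$segments)
  cat(sprintf("<bgdcm_cohort> %d subjects x %d segment pairs (seed %d)\n",
              length(x$subjects), nseg, x$seed))
  cat("  OFF/ON ratios:",
      paste(sprintf("%s=%.3g", names(x$off_ratios), x$off_ratios),
            collapse = " "), "\n")
  invisible(x)
}

#' Simulate a multichannel segment recording from a parameter set
#'
#' Generates the observed-layout recording (1 cortical EEG channel, 3
#' bipolar contacts per deep site) from the linearised stochastic circuit
#' driven by seeded white + 1/f innovations.  The default `"spectral"`
#' method synthesises the source depolarisation signals in the frequency
#' domain from the exact transfer functions (evaluated on a coarse grid
#' and interpolated, the transfer function being smooth); `"euler"`
#' integrates the delay stochastic system with Euler-Maruyama steps (slow,
#' used as an independent oracle).  Deep sources are mixed onto their
#' three contacts with geometrically decaying loadings plus independent
#' sensor noise at `sensor_noise` of the projected source variance.
#'
#' @param circuit a `bgdcm_circuit`
#' @param theta condition-resolved `bgdcm_theta`
#' @param duration seconds (default 50)
#' @param fs sampling rate, Hz (default 1000)
#' @param seed integer seed
#' @param condition recorded condition label
#' @param method `"spectral"` or `"euler"`
#' @param loadings contact loading vector for the deep sites
#' @param sensor_noise sensor-noise variance as a fraction of each
#'   contact's projected source variance
#' @param subject,segment identifiers carried into the recording
#' @return a `bgdcm_recording` with channels
#'   `ctx, stn1..3, gpi1..3`
#' @export
simulate_recording <- function(circuit, theta, duration = 50, fs = 1000,
                               seed = 1L, condition = c("off", "on"),
                               method = c("spectral", "euler"),
                               loadings = c(1, 0.7, 0.4),
                               sensor_noise = 0.1,
                               subject = 1L, segment = 1L) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  n <- round(duration * fs)
  set.seed(seed)
  obs_pops <- c(ctx = "ctx.py", stn = "stn", gpi = "gpi")

  if (method == "spectral") {
    ss <- linearize(circuit, theta)
    if (!ss$stable) stopf("unstable parameter set (max Re %.3g)", ss$max_re)
    idx <- ss$idx
    V <- matrix(0, length(obs_pops), idx$nx)
    for (i in seq_along(obs_pops)) {
      p <- match(obs_pops[i], ss$pops)
      V[i, idx$ve[p]] <- 1; V[i, idx$vi[p]] <- -1
    }
    ## transfer functions: exact on the synthesis grid below 100 Hz (where
    ## the dynamics live and resonances are sharp), interpolated from a
    ## 2 Hz grid above
    f <- seq(0, fs / 2, by = 1 / duration)
    nf <- length(f)
    low <- f <= 100
    fg_high <- unique(c(seq(100, fs / 2, by = 2), fs / 2))
    Tlow <- transfer_stack(ss, V, f[low])
    Thigh <- transfer_stack(ss, V, fg_high)
    gu <- innovation_spectrum(f, theta$noise)
    amp <- sqrt(n * fs * gu / 2)
    src <- matrix(0, length(obs_pops), n)
    Xs <- matrix(0i, length(obs_pops), nf)
    for (j in seq_len(ncol(ss$B))) {
      re <- rnorm(nf); im <- rnorm(nf)
      X <- complex(real = amp * re, imaginary = amp * im)
      X[1] <- 0                                  # innovations are zero-mean
      if (n %% 2 == 0) X[nf] <- sqrt(2) * amp[nf] * re[nf]
      for (i in seq_along(obs_pops)) {
        Tij <- complex(real = numeric(nf), imaginary = numeric(nf))
        Tij[low] <- Tlow[i, j, ]
        Tij[!low] <- approx(fg_high, Re(Thigh[i, j, ]), xout = f[!low])$y +
          1i * approx(fg_high, Im(Thigh[i, j, ]), xout = f[!low])$y
        Xs[i, ] <- Xs[i, ] + Tij * X
      }
    }
    for (i in seq_along(obs_pops)) {
      full <- c(Xs[i, ], Conj(rev(Xs[i, 2:(nf - 1L + n %% 2)])))
      src[i, ] <- Re(fft(full, inverse = TRUE)) / n
    }
  } else {
    X <- simulate_states(circuit, theta, duration, fs, seed = seed)
    idx <- state_index(circuit)
    src <- matrix(0, length(obs_pops), n)
    for (i in seq_along(obs_pops)) {
      p <- match(obs_pops[i], circuit$pops$id)
      src[i, ] <- X[idx$ve[p], ] - X[idx$vi[p], ]
    }
  }
  rownames(src) <- names(obs_pops)

  mix_site <- function(v) {
    out <- matrix(0, length(loadings), n)
    for (c_i in seq_along(loadings)) {
      sig <- loadings[c_i] * v
      out[c_i, ] <- sig + rnorm(n, 0, sqrt(sensor_noise * var(sig)))
    }
    out
  }
  ctx <- src["ctx", ] + rnorm(n, 0, sqrt(sensor_noise * var(src["ctx", ])))
  stn <- mix_site(src["stn", ])
  gpi <- mix_site(src["gpi", ])
  channels <- rbind(ctx = ctx, stn)
  channels <- rbind(channels, gpi)
  rownames(channels) <- c("ctx", paste0("stn", 1:3), paste0("gpi", 1:3))
  segment_recording(channels, fs, condition, subject, segment)
}

#' Write / read a cohort container (JSON)
#'
#' Lossless round trip of the full cohort including ground-truth parameter
#' sets and recording seeds.  A truncated or malformed file raises an
#' error rather than returning a partial object; a version mismatch is an
#' explicit incompatibility error.
#'
#' @param cohort a `bgdcm_cohort`
#' @param path file path
#' @return `read_cohort` returns a `bgdcm_cohort`
#' @export
write_cohort <- function(cohort, path) {
  obj <- unclass(cohort)
  listify_theta <- function(th) lapply(unclass(th), as.list)
  obj$off_ratios <- as.list(obj$off_ratios)
  obj$subjects <- lapply(obj$subjects, function(s) {
    s$segments <- lapply(s$segments, function(g) {
      g$theta_on <- listify_theta(g$theta_on)
      g$theta_off <- listify_theta(g$theta_off)
      g
    })
    s
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stopf("malformed cohort file: %s",
                                            conditionMessage(e)))
  if (is.null(obj$format_version))
    stopf("malformed cohort file: missing version field")
  if (obj$format_version != cohort_format_version)
    stopf("incompatible cohort file version %s", obj$format_version)
  relist_theta <- function(th)
    structure(list(syn = unlist(th$syn), gains = unlist(th$gains),
                   mods = unlist(th$mods), obs = unlist(th$obs),
                   noise = unlist(th$noise)), class = "bgdcm_theta")
  obj$off_ratios <- unlist(obj$off_ratios)
  obj$subjects <- lapply(obj$subjects, function(s) {
    s$segments <- lapply(s$segments, function(g) {
      g$theta_on <- relist_theta(g$theta_on)
      g$theta_off <- relist_theta(g$theta_off)
      g
    })
    s
  })
  structure(obj, class = "bgdcm_cohort")
}
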