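## Data features: reduce raw multichannel segments to the cross-spectral
## densities the model is fitted to.  Deep-site contacts are summarised by
## their first principal component (leading eigenvariate), the three
## resulting series are modelled by a shrinkage-regularised VAR(8), and the
## VAR coefficients and innovation covariance are transformed to the
## spectral matrix
##    S(w) = H(w) E H(w)*,   H(w) = (I - sum_k A_k e^{-i w k / fs})^{-1}.

#' First principal component of a contact matrix
#'
#' Leading eigenvariate of the channel covariance, computed by singular
#' value decomposition of the row-centred matrix.  The sign is fixed so the
#' loading with the largest magnitude is positive.
#'
#' @param X channels x samples matrix (>= 2 channels, more samples than
#'   channels)
#' @return list with `series` (length `ncol(X)`), `variance_fraction`
#'   (share of total variance explained, in (0, 1]) and `loadings`
#' @export
first_principal_component <- function(X) {
  if (nrow(X) < 2L) stopf("need at least 2 channels")
  if (ncol(X) <= nrow(X)) stopf("need more samples than channels")
  Xc <- X - rowMeans(X)
  if (any(apply(Xc, 1, function(r) all(abs(r) < .Machine$double.eps * 10))))
    stopf("constant channel(s) in contact matrix")
  sv <- svd(Xc, nu = nrow(X), nv = 0)
  w <- sv$u[, 1]
  if (w[which.max(abs(w))] < 0) w <- -w
  list(series = drop(w %*% Xc),
       variance_fraction = sv$d[1]^2 / sum(sv$d^2),
       loadings = w)
}

#' Fit a shrinkage-regularised vector autoregression
#'
#' Conditional-mean (ridge/MAP) estimate of the VAR coefficient matrices
#' under independent zero-mean Gaussian shrinkage priors on every
#' autoregressive coefficient, with the innovation covariance estimated
#' from the residuals.  Deterministic given the data.
#'
#' @param Y channels x samples matrix
#' @param p model order (default 8)
#' @param lambda shrinkage prior precision on the coefficients, relative to
#'   the (per-channel standardised) innovation precision; `lambda -> Inf`
#'   drives all coefficients to zero
#' @return object of class `bgdcm_var`: list with `A` (list of p
#'   channel x channel matrices), `E` (innovation covariance), `p`, `fs`
#'   attribute left to the caller
#' @export
fit_var <- function(Y, p = 8L, lambda = 1) {
  d <- nrow(Y); T <- ncol(Y)
  if (T <= 10L * p) stopf("too few samples (T = %d) for order %d", T, p)
  Yc <- Y - rowMeans(Y)
  ## standardise per channel so the shrinkage prior is scale-free
  sdv <- apply(Yc, 1, sd)
  if (any(sdv == 0)) stopf("constant channel in VAR input")
  Ys <- Yc / sdv
  nT <- T - p
  resp <- t(Ys[, (p + 1):T, drop = FALSE])            # nT x d
  X <- matrix(0, nT, d * p)
  for (k in seq_len(p))
    X[, ((k - 1) * d + 1):(k * d)] <- t(Ys[, (p + 1 - k):(T - k), drop = FALSE])
  G <- crossprod(X) + diag(lambda, d * p)
  if (rcond(G) < 1e-12) stopf("rank-deficient lagged regressors")
  Bhat <- solve(G, crossprod(X, resp))                # (d*p) x d
  resid <- resp - X %*% Bhat
  Es <- crossprod(resid) / (nT - 1)
  ## undo standardisation: A_k[i,j] acts on channel j driving channel i
  A <- vector("list", p)
  D <- diag(sdv, d); Dinv <- diag(1 / sdv, d)
  for (k in seq_len(p)) {
    Ak <- t(Bhat[((k - 1) * d + 1):(k * d), , drop = FALSE])   # d x d, rows=target
    A[[k]] <- D %*% Ak %*% Dinv
  }
  E <- D %*% Es %*% D
  structure(list(A = A, E = (E + t(E)) / 2, p = p, lambda = lambda),
            class = "bgdcm_var")
}

#' Cross-spectral density of a fitted VAR model
#'
#' `H(w) = (I - sum_k A_k e^{-i w k / fs})^{-1}`; `S(w) = H E H*`.  The
#' normalisation is fixed by the white-noise identity: a VAR with zero
#' coefficients and innovation covariance `E` has constant spectral matrix
#' `E` (power per sample, two-sided convention divided by `fs` on request).
#'
#' @param model a `bgdcm_var`
#' @param freqs frequency grid (Hz)
#' @param fs sampling rate (Hz)
#' @param per_hz divide by `fs` to obtain a density per Hz comparable to a
#'   periodogram (default FALSE: per-sample convention `S = E` for white
#'   noise)
#' @return a `bgdcm_csd`; near-singular AR polynomial frequencies are
#'   reported via attribute `flagged`
#' @export
var_csd <- function(model, freqs, fs, per_hz = FALSE) {
  d <- nrow(model$E)
  labels <- rownames(model$E) %||% paste0("ch", seq_len(d))
  Ac <- array(unlist(model$A, use.names = FALSE), c(d, d, model$p))
  res <- var_spec_cpp(Ac, unname(model$E), freqs, fs)
  S <- aperm(res$S, c(3, 1, 2))
  flagged <- as.numeric(res$flagged)
  if (per_hz) S <- S / fs
  out <- new_csd(freqs, S, labels)
  out$fs <- fs
  out$var_order <- model$p
  attr(out, "flagged") <- flagged
  out
}

#' Low-pass filter and decimate a series
#'
#' Windowed-sinc (Hamming) anti-alias filter with cutoff at 80% of the new
#' Nyquist frequency, followed by subsampling.  Used before the VAR fit so
#' the analysis band occupies an appreciable fraction of the Nyquist range
#' (an autoregression of modest order cannot represent narrow resonances at
#' a tiny fraction of the sampling rate).
#'
#' @param x numeric series
#' @param factor integer decimation factor
#' @return series of length `floor(length(x) / factor)`
#' @export
decimate_series <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stopf("decimation factor must be >= 1")
  if (factor == 1L) return(x)
  h <- decimation_kernel(factor)
  xf <- stats::filter(x, h, sides = 2)
  ## pad-filtered edges: fall back to the raw series there
  xf[is.na(xf)] <- x[is.na(xf)]
  as.numeric(xf[seq(1L, length(x), by = factor)])
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

## windowed-sinc anti-alias kernel shared by decimate_series and the
## operator-consistent inversion (which needs its exact frequency response)
decimation_kernel <- function(factor) {
  cutoff <- 0.85 / (2 * factor)           # cycles per (original) sample
  half <- 12L * factor                    # long kernel: narrow transition band
  t <- seq(-half, half)
  h <- 2 * cutoff * sinc(2 * cutoff * t) *
    (0.54 + 0.46 * cos(pi * t / half))    # Hamming window
  h / sum(h)
}

#' Power gain of the decimation anti-alias filter
#'
#' `|H(f)|^2` of the windowed-sinc kernel used by [decimate_series()],
#' evaluated at frequencies `f` (Hz) for original sampling rate `fs`.
#'
#' @param factor integer decimation factor
#' @param f frequencies (Hz)
#' @param fs original sampling rate (Hz)
#' @return numeric vector of squared magnitudes
#' @export
decimation_filter_gain <- function(factor, f, fs) {
  h <- decimation_kernel(factor)
  t <- seq(-((length(h) - 1L) %/% 2L), (length(h) - 1L) %/% 2L)
  vapply(f, function(fi) abs(sum(h * exp(-2i * pi * fi / fs * t)))^2, 0)
}

#' Segment recording container
#'
#' @param channels labelled channels x samples matrix (one cortical EEG
#'   channel `ctx`, three bipolar contacts per deep site: `stn1..3`,
#'   `gpi1..3`)
#' @param fs sampling rate (Hz)
#' @param condition `"off"` or `"on"`
#' @param subject,segment identifiers
#' @return object of class `bgdcm_recording`
#' @export
segment_recording <- function(channels, fs = 1000, condition = c("off", "on"),
                              subject = 1L, segment = 1L) {
  condition <- match.arg(condition)
  stopifnot(is.matrix(channels), !is.null(rownames(channels)))
  structure(list(channels = channels, fs = fs, condition = condition,
                 subject = subject, segment = segment),
            class = "bgdcm_recording")
}

#' @export
print.bgdcm_recording <- function(x, ...) {
  cat(sprintf("<bgdcm_recording> subject %s segment %s (%s): %d ch x %.1f s @ %g Hz\n",
              x$subject, x$segment, toupper(x$condition), nrow(x$channels),
              ncol(x$channels) / x$fs, x$fs))
  invisible(x)
}

#' Write / read a segment recording (CSV + JSON sidecar)
#'
#' The channel matrix goes to a CSV (one row per channel, first column the
#' channel label); sampling rate, condition and identifiers go to a JSON
#' sidecar at `<path>.json`.  Round trips preserve values to 15
#' significant digits.
#'
#' @param recording a `bgdcm_recording`
#' @param path CSV file path
#' @return `read_recording` returns a `bgdcm_recording`
#' @export
write_recording <- function(recording, path) {
  df <- data.frame(channel = rownames(recording$channels),
                   recording$channels, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double")
  meta <- list(format_version = 1L, fs = recording$fs,
               condition = recording$condition,
               subject = recording$subject, segment = recording$segment,
               labels = rownames(recording$channels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stopf("incompatible recording sidecar version")
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  ch <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(ch) <- list(raw[[1]], NULL)
  segment_recording(ch[meta$labels, , drop = FALSE], fs = meta$fs,
                    condition = meta$condition, subject = meta$subject,
                    segment = meta$segment)
}

#' Extract cross-spectral data features from a recording
#'
#' The full feature pipeline: first principal component of each deep site's
#' three bipolar contacts, assembly of the three representative series
#' (cortex, STN, GPi), shrinkage VAR fit of order `p`, spectral transform,
#' and restriction to the analysis band.  Deterministic.
#'
#' @param segment a `bgdcm_recording`
#' @param band analysis band in Hz (default 13-35)
#' @param p VAR order (default 8)
#' @param freq_step grid step within the band (Hz)
#' @param lambda shrinkage precision passed to [fit_var()]
#' @param decimate_to target sampling rate (Hz) for the VAR stage; the
#'   series are anti-alias filtered and decimated by the nearest integer
#'   factor so the beta band sits well inside the reduced Nyquist range
#' @return a `bgdcm_csd` on the band grid with channels `ctx`, `stn`, `gpi`;
#'   attribute `pca` holds each site's variance fraction
#' @export
extract_features <- function(segment, band = c(13, 35), p = 8L,
                             freq_step = 1, lambda = 1, decimate_to = 125) {
  ch <- segment$channels
  sites <- list(stn = grep("^stn", rownames(ch)),
                gpi = grep("^gpi", rownames(ch)))
  ctx_i <- grep("^ctx", rownames(ch))
  if (length(ctx_i) != 1L)
    stopf("expected exactly one cortical channel, found %d", length(ctx_i))
  pcs <- lapply(sites, function(ix) {
    if (length(ix) != 3L) stopf("each deep site must have 3 bipolar contacts")
    first_principal_component(ch[ix, , drop = FALSE])
  })
  fac <- max(1L, round(segment$fs / decimate_to))
  fs_d <- segment$fs / fac
  if (fs_d < 2 * band[2]) stopf("decimated rate %g Hz below twice the band", fs_d)
  Y <- rbind(ctx = decimate_series(ch[ctx_i, ] - mean(ch[ctx_i, ]), fac),
             stn = decimate_series(pcs$stn$series, fac),
             gpi = decimate_series(pcs$gpi$series, fac))
  model <- fit_var(Y, p = p, lambda = lambda)
  rownames(model$E) <- colnames(model$E) <- rownames(Y)
  freqs <- seq(band[1], band[2], by = freq_step)
  out <- var_csd(model, freqs, fs_d)
  out$band <- band
  out$fs <- fs_d                 # rate the VAR refers to
  out$var_order <- p
  out$decimation <- list(factor = fac, fs_raw = segment$fs)
  attr(out, "pca") <- vapply(pcs, `[[`, 0, "variance_fraction")
  attr(out, "var_model") <- model
  out
}

#' Reduce a full-band cross-spectral density through a VAR(p) of the process
#'
#' The population analogue of the data-feature pipeline: from a model CSD
#' sampled on a full grid up to the (decimated) Nyquist frequency, compute
#' the process autocovariance sequence, solve the multivariate Yule-Walker
#' equations for the order-`p` autoregression, and return that VAR's
#' spectrum on the analysis grid.  Applying the same model-order reduction
#' to predictions as the data undergo makes the prediction-data comparison
#' operator-consistent, so the (deliberate) smoothing of an order-8
#' autoregression does not masquerade as a parameter effect.
#'
#' @param csd_full a `bgdcm_csd` on a regular grid from 0 to `fs/2`
#' @param p VAR order
#' @param fs sampling rate (Hz) of the process the grid refers to
#' @param freqs output frequency grid (Hz)
#' @return a `bgdcm_csd` on `freqs` (per-sample convention, like
#'   [var_csd()])
#' @export
csd_var_reduce <- function(csd_full, p, fs, freqs) {
  f <- csd_full$freqs
  df <- f[2] - f[1]
  d <- length(csd_full$labels)
  nf <- length(f)
  ## R_k = int_{-Ny}^{Ny} S(f) e^{i 2 pi f k / fs} df
  ##     = 2 int_0^{Ny} Re(S(f) e^{i 2 pi f k / fs}) df  (S(-f) = conj S(f));
  ## trapezoid weights on the one-sided grid
  wts <- rep(df, nf); wts[c(1, nf)] <- df / 2
  Sflat <- matrix(csd_full$S, nf, d * d)           # column (a,b) -> a+(b-1)d
  Ph <- exp(2i * pi * outer(f, 0:p) / fs)
  M <- crossprod(Sflat * wts, Ph)                  # d^2 x (p+1)
  R <- lapply(0:p, function(k) matrix(2 * Re(M[, k + 1]), d, d))
  G <- matrix(0, d * p, d * p)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    blk <- if (k >= j) R[[k - j + 1]] else t(R[[j - k + 1]])
    G[((j - 1) * d + 1):(j * d), ((k - 1) * d + 1):(k * d)] <- blk
  }
  Brow <- do.call(cbind, R[2:(p + 1)])             # d x dp
  Arow <- t(solve(G, t(Brow)))                     # d x dp
  A <- lapply(seq_len(p), function(j)
    Arow[, ((j - 1) * d + 1):(j * d), drop = FALSE])
  E <- R[[1]]
  for (j in seq_len(p)) E <- E - A[[j]] %*% t(R[[j + 1]])
  E <- (E + t(E)) / 2
  model <- structure(list(A = A, E = E, p = p, lambda = 0),
                     class = "bgdcm_var")
  rownames(model$E) <- colnames(model$E) <- csd_full$labels
  out <- var_csd(model, freqs, fs)
  out$band <- csd_full$band
  out
}

#' Averaged-periodogram (Welch) cross-spectral estimate
#'
#' Nonparametric CSD estimate used as the independent oracle against the
#' parametric routes: the data are split into `nseg` non-overlapping
#' Hann-tapered segments and raw cross-periodograms are averaged.  Returned
#' in the per-sample convention of [var_csd()] (white noise with covariance
#' `E` gives a flat spectrum `E`).
#'
#' @param Y channels x samples matrix
#' @param fs sampling rate (Hz)
#' @param freqs frequencies (Hz) at which to interpolate the estimate
#' @param nseg number of (non-overlapping) segment lengths the data are cut
#'   into; with `overlap = TRUE` (default) windows advance by half a
#'   segment, giving `2 * nseg - 1` tapered windows
#' @param overlap use 50% window overlap
#' @return a `bgdcm_csd`
#' @export
welch_csd <- function(Y, fs, freqs, nseg = 16L, overlap = TRUE) {
  d <- nrow(Y); T <- ncol(Y)
  L <- T %/% nseg
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  U <- sum(win^2)
  fgrid <- (seq_len(L) - 1) * fs / L
  starts <- seq(1L, T - L + 1L, by = if (overlap) max(1L, L %/% 2L) else L)
  acc <- array(0i, c(L, d, d))
  for (s0 in starts) {
    seg <- Y[, s0:(s0 + L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Fw <- t(apply(seg, 1, function(r) fft(r * win)))
    if (d == 1L) Fw <- matrix(Fw, nrow = 1L)
    for (i in seq_len(d)) for (j in seq_len(d))
      acc[, i, j] <- acc[, i, j] + Fw[i, ] * Conj(Fw[j, ])
  }
  acc <- acc / (length(starts) * U)
  S <- array(0i, c(length(freqs), d, d))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    re <- approx(fgrid, Re(acc[, i, j]), xout = freqs)$y
    im <- approx(fgrid, Im(acc[, i, j]), xout = freqs)$y
    S[, i, j] <- re + 1i * im
  }
  new_csd(freqs, S, rownames(Y) %||% paste0("ch", seq_len(d)))
}

#' @importFrom stats approx fft
NULL
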