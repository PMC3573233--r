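## Spectral forward model: linearise the neural-mass dynamics at the fixed
## point and propagate innovation spectra through the transfer function
##    T(w) = C (iwI - sum_d A_d e^{-iw delta_d})^{-1} B
## to predict the auto/cross-spectral densities of the observed channels.
## Conduction delays are kept exact as per-block phase factors.

#' Linearise the circuit at a fixed point
#'
#' Computes the Jacobian of the vector field, split into blocks by distinct
#' conduction delay (delayed presynaptic firing contributes to the block of
#' its delay), the innovation input matrix `B` and the observation matrix
#' `C` built from the observation map and gains.
#'
#' @inheritParams state_derivative
#' @param x0 linearisation point (default: origin, the fixed point of the
#'   centred system)
#' @return an object of class `bgdcm_statespace`: list with `delays`
#'   (seconds, first is 0), `A` (list of matrices), `B`, `C`, `stable`
#'   (logical: zero-delay aggregate eigenvalues in the left half-plane) and
#'   `max_re` (largest real part)
#' @export
linearize <- function(circuit, theta, x0 = NULL) {
  idx <- state_index(circuit)
  if (is.null(x0)) x0 <- numeric(idx$nx)
  syn <- theta$syn
  conn <- circuit$connections
  gain <- theta$gains[conn$id]
  pid <- circuit$pops$id
  ke <- syn[["kappa_e"]]; ki <- syn[["kappa_i"]]

  delays <- sort(unique(c(0, conn$delay)))
  A <- lapply(delays, function(d) matrix(0, idx$nx, idx$nx))
  names(A) <- paste0("d", delays)

  ## zero-delay self terms (channel kinetics)
  A0 <- A[[1]]
  A0[cbind(idx$ve, idx$ze)] <- 1
  A0[cbind(idx$vi, idx$zi)] <- 1
  A0[cbind(idx$ze, idx$ve)] <- -ke^2
  A0[cbind(idx$ze, idx$ze)] <- -2 * ke
  A0[cbind(idx$zi, idx$vi)] <- -ki^2
  A0[cbind(idx$zi, idx$zi)] <- -2 * ki
  A[[1]] <- A0

  sprime <- sigmoid_slope(pop_depolarisation(x0, idx), syn)
  from_i <- match(conn$from, pid)
  to_i <- match(conn$to, pid)
  for (k in seq_len(nrow(conn))) {
    b <- match(conn$delay[k], delays)
    kH <- if (conn$sign[k] > 0) ke * syn[["He"]] else ki * syn[["Hi"]]
    row <- if (conn$sign[k] > 0) idx$ze[to_i[k]] else idx$zi[to_i[k]]
    w <- kH * gain[k] * sprime[from_i[k]]
    A[[b]][row, idx$ve[from_i[k]]] <- A[[b]][row, idx$ve[from_i[k]]] + w
    A[[b]][row, idx$vi[from_i[k]]] <- A[[b]][row, idx$vi[from_i[k]]] - w
  }

  innov <- circuit$innovations
  iw <- rep(1, length(innov))
  if (!is.null(circuit$innovation_weights))
    iw <- unname(unlist(circuit$innovation_weights)[innov])
  B <- matrix(0, idx$nx, length(innov),
              dimnames = list(NULL, innov))
  B[cbind(idx$ze[match(innov, pid)], seq_along(innov))] <-
    ke * syn[["He"]] * sqrt(iw)

  chan <- circuit$observation$channel
  C <- matrix(0, length(chan), idx$nx, dimnames = list(chan, NULL))
  for (i in seq_along(chan)) {
    pop <- match(circuit$observation$pop[i], pid)
    g <- theta$obs[[chan[i]]]
    C[i, idx$ve[pop]] <- g
    C[i, idx$vi[pop]] <- -g
  }

  Atot <- Reduce(`+`, A)
  ev <- eigen(Atot, only.values = TRUE)$values
  structure(list(delays = delays, A = A, B = B, C = C,
                 pops = pid, idx = idx,
                 stable = max(Re(ev)) < 0, max_re = max(Re(ev))),
            class = "bgdcm_statespace")
}

aggregate_jacobian <- function(circuit, theta, x0 = NULL) {
  ss <- linearize(circuit, theta, x0)
  Reduce(`+`, ss$A)
}

## M(w) = iwI - sum_d A_d e^{-iw delta_d}; shared by all transfer products.
freq_matrix <- function(ss, omega) {
  nx <- nrow(ss$A[[1]])
  M <- diag(1i * omega, nx)
  for (b in seq_along(ss$A))
    M <- M - ss$A[[b]] * exp(-1i * omega * ss$delays[b])
  M
}

## Batched frequency responses V * M(w)^{-1} * B over a frequency grid
## (compiled); returns complex array (nrow(V) x ncol(B) x nfreq).
transfer_stack <- function(ss, V, freqs) {
  nx <- nrow(ss$A[[1]])
  Ac <- array(unlist(ss$A, use.names = FALSE), c(nx, nx, length(ss$A)))
  transfer_stack_cpp(Ac, ss$delays, ss$B, V, 2 * pi * freqs)
}

#' Channel-by-innovation transfer matrix at one angular frequency
#'
#' @param ss a `bgdcm_statespace` from [linearize()]
#' @param omega angular frequency (rad/s)
#' @return complex matrix (channels x innovation inputs)
#' @export
transfer_matrix <- function(ss, omega) {
  M <- freq_matrix(ss, omega)
  out <- tryCatch(solve(M, ss$B), error = function(e) NULL)
  if (is.null(out))
    stopf("transfer matrix singular at omega = %g rad/s", omega)
  ss$C %*% out
}

## innovation and channel-noise spectra (two-sided, arbitrary power units);
## the 1/f component is clamped below 1 Hz so band-limited predictions stay
## finite at DC.
innovation_spectrum <- function(f, noise) {
  noise[["u_white"]] + noise[["u_pink"]] / pmax(f, 1)
}

channel_noise_spectrum <- function(f, noise) {
  noise[["c_white"]] + noise[["c_pink"]] / pmax(f, 1)
}

#' Predict observed-channel cross-spectral densities
#'
#' The generative likelihood mapping: for each frequency,
#' `S(w) = T(w) G_u(w) T(w)* + G_c(w) I`, where `G_u` is the (white + 1/f)
#' innovation spectrum at each innovation site and `G_c` the per-channel
#' measurement noise spectrum.  The result is Hermitian positive
#' semidefinite by construction.
#'
#' @inheritParams state_derivative
#' @param freqs frequency grid (Hz)
#' @param condition `"on"` or `"off"` (resolves condition modulators)
#' @param channel_noise include the additive channel-noise spectrum
#' @return a `bgdcm_csd`: list with `freqs`, complex array `S`
#'   (`freq x channel x channel`), `labels`, `band`
#' @export
predict_csd <- function(circuit, theta, freqs = 13:35,
                        condition = c("on", "off"), channel_noise = TRUE) {
  condition <- match.arg(condition)
  th <- condition_theta(theta, condition)
  ss <- linearize(circuit, th)
  if (!ss$stable)
    stopf("unstable linearisation (max Re eigenvalue %.3g)", ss$max_re)
  nch <- nrow(ss$C)
  nf <- length(freqs)
  gu <- innovation_spectrum(freqs, th$noise)
  gc <- if (channel_noise) channel_noise_spectrum(freqs, th$noise) else
    rep(0, nf)
  nx <- nrow(ss$A[[1]])
  Ac <- array(unlist(ss$A, use.names = FALSE), c(nx, nx, length(ss$A)))
  cube <- csd_stack_cpp(Ac, ss$delays, ss$B, ss$C, 2 * pi * freqs, gu, gc)
  S <- aperm(cube, c(3, 1, 2))
  new_csd(freqs, S, rownames(ss$C))
}

#' Per-subpopulation depolarisation spectra
#'
#' Innovation-driven power spectra of every subpopulation's depolarisation
#' (v_e - v_i), including hidden sources, via the same transfer machinery
#' as [predict_csd()] but reading out all states.  Used by the beta-power
#' and lesion analyses.
#'
#' @inheritParams predict_csd
#' @return matrix `freq x subpopulation` of real spectral densities
#' @export
source_spectra <- function(circuit, theta, freqs = 13:35,
                           condition = c("on", "off")) {
  condition <- match.arg(condition)
  th <- condition_theta(theta, condition)
  ss <- linearize(circuit, th)
  if (!ss$stable)
    stopf("unstable linearisation (max Re eigenvalue %.3g)", ss$max_re)
  idx <- ss$idx
  npop <- idx$npop
  V <- matrix(0, npop, nrow(ss$A[[1]]))
  V[cbind(seq_len(npop), idx$ve)] <- 1
  V[cbind(seq_len(npop), idx$vi)] <- -1
  gu <- innovation_spectrum(freqs, th$noise)
  out <- matrix(0, length(freqs), npop, dimnames = list(NULL, ss$pops))
  Qs <- transfer_stack(ss, V, freqs)
  for (i in seq_along(freqs))
    out[i, ] <- gu[i] * rowSums(abs(matrix(Qs[, , i], npop))^2)
  out
}

## --- cross-spectral container ----------------------------------------------

new_csd <- function(freqs, S, labels, band = c(13, 35)) {
  dimnames(S) <- list(NULL, labels, labels)
  structure(list(freqs = freqs, S = S, labels = labels, band = band),
            class = "bgdcm_csd")
}

#' @export
print.bgdcm_csd <- function(x, ...) {
  cat(sprintf("<bgdcm_csd> %d frequencies (%g-%g Hz), channels: %s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

band_mask <- function(csd, band = csd$band) {
  csd$freqs >= band[1] & csd$freqs <= band[2]
}

#' Restrict a cross-spectral object to its analysis band
#'
#' @param csd a `bgdcm_csd`
#' @param band length-2 numeric, Hz
#' @return a `bgdcm_csd` on the masked grid
#' @export
csd_band <- function(csd, band = csd$band) {
  keep <- csd$freqs >= band[1] & csd$freqs <= band[2]
  new_csd(csd$freqs[keep], csd$S[keep, , , drop = FALSE], csd$labels, band)
}

#' Write / read a cross-spectral container (JSON)
#'
#' Lossless round trip of the frequency grid, complex matrices (stored as
#' real and imaginary parts), channel labels and band.
#'
#' @param csd a `bgdcm_csd`
#' @param path file path
#' @return `read_csd` returns a `bgdcm_csd`
#' @export
write_csd <- function(csd, path) {
  obj <- list(format_version = 1L, freqs = csd$freqs, labels = csd$labels,
              band = csd$band, re = Re(csd$S), im = Im(csd$S))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_csd
#' @export
read_csd <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("malformed CSD file: %s",
                                            conditionMessage(e)))
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stopf("incompatible CSD file version")
  nch <- length(obj$labels)
  nf <- length(obj$freqs)
  S <- array(as.complex(obj$re), c(nf, nch, nch)) +
    1i * array(as.numeric(obj$im), c(nf, nch, nch))
  new_csd(obj$freqs, S, obj$labels, obj$band)
}

#' Export a cross-spectral object as a long-format CSV
#'
#' One row per (frequency, channel pair): columns `f`, `chan_i`, `chan_j`,
#' `re`, `im`.
#'
#' @inheritParams write_csd
#' @export
csd_to_csv <- function(csd, path) {
  grid <- expand.grid(i = seq_along(csd$labels), j = seq_along(csd$labels),
                      k = seq_along(csd$freqs))
  out <- data.frame(f = csd$freqs[grid$k],
                    chan_i = csd$labels[grid$i],
                    chan_j = csd$labels[grid$j],
                    re = Re(csd$S[cbind(grid$k, grid$i, grid$j)]),
                    im = Im(csd$S[cbind(grid$k, grid$i, grid$j)]))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
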