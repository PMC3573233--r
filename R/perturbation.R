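## Contribution (sensitivity) and in-silico lesion analyses: how much a
## small change in a connection gain alters band-limited oscillatory power
## throughout the circuit, and what removing the STN (or resetting single
## connections to their treated values) does to that power.

## map each source to its principal (output) subpopulation
principal_pops <- function(circuit) {
  pick <- function(src) {
    pops <- circuit$pops[circuit$pops$source == src, ]
    if (nrow(pops) == 1L) pops$id else pops$id[pops$kind == "pyramidal"]
  }
  vapply(circuit$sources, pick, "")
}

#' Band-limited oscillatory power throughout the circuit
#'
#' Integrates the innovation-driven depolarisation spectrum of each
#' source's principal subpopulation over the analysis band (hidden sources
#' included, via the same transfer machinery as the observed channels:
#' channel noise plays no part).  The network summary `beta` is the sum of
#' per-source band powers.
#'
#' @inheritParams predict_csd
#' @param band frequency band (Hz)
#' @param freq_step grid step (Hz)
#' @return object of class `bgdcm_beta`: list with `per_source` (named
#'   band powers), `beta` (their sum), `freqs`, `spectra`
#'   (frequency x source matrix)
#' @export
beta_power <- function(circuit, theta, condition = c("off", "on"),
                       band = c(13, 35), freq_step = 1) {
  condition <- match.arg(condition)
  freqs <- seq(band[1], band[2], by = freq_step)
  sp <- source_spectra(circuit, theta, freqs, condition)
  pp <- principal_pops(circuit)
  spec <- sp[, pp, drop = FALSE]
  colnames(spec) <- names(pp)
  per_source <- apply(spec, 2, function(y) trapz(freqs, y))
  structure(list(per_source = per_source, beta = sum(per_source),
                 freqs = freqs, spectra = spec, condition = condition),
            class = "bgdcm_beta")
}

#' @export
print.bgdcm_beta <- function(x, ...) {
  cat(sprintf("<bgdcm_beta> network beta power (%s): %.4g\n",
              toupper(x$condition), x$beta))
  print(signif(x$per_source, 4))
  invisible(x)
}

#' Contribution of a connection to beta power (d beta / d c)
#'
#' Central finite difference of the network beta power with respect to one
#' connection's gain, at a relative step `delta`: the scalar contribution
#' is the band-averaged, source-averaged derivative, and the frequency
#' profile is the per-frequency derivative averaged (unweighted) across
#' sources.  Positive values mean a small strengthening of the connection
#' promotes beta activity.  If either stencil point is dynamically
#' unstable the step is shrunk once (by 10x) before failing.
#'
#' @inheritParams beta_power
#' @param connection connection id (e.g. `"gpe_stn"`)
#' @param delta relative finite-difference step (default 1e-3)
#' @return list with `dbeta_dc` (scalar), `profile` (per-frequency
#'   derivative, averaged over sources), `freqs`, `delta_used`
#' @export
contribution <- function(circuit, theta, connection,
                         condition = c("off", "on"), band = c(13, 35),
                         freq_step = 1, delta = 1e-3) {
  condition <- match.arg(condition)
  if (!connection %in% circuit$connections$id)
    stopf("unknown connection '%s'", connection)
  c0 <- theta$gains[[connection]]
  eval_at <- function(g) {
    th <- theta; th$gains[[connection]] <- g
    beta_power(circuit, th, condition, band, freq_step)
  }
  for (d in c(delta, delta / 10)) {
    h <- c0 * d
    bp <- tryCatch(list(eval_at(c0 + h), eval_at(c0 - h)),
                   error = function(e) NULL)
    if (!is.null(bp)) {
      nsrc <- ncol(bp[[1]]$spectra)
      profile <- rowMeans(bp[[1]]$spectra - bp[[2]]$spectra) / (2 * h)
      return(list(dbeta_dc = mean(profile),
                  profile = profile, freqs = bp[[1]]$freqs,
                  connection = connection, delta_used = d))
    }
  }
  stopf("instability within the finite-difference stencil for '%s'", connection)
}

#' Contribution profiles for every extrinsic connection
#'
#' @inheritParams contribution
#' @return data.frame: per connection the scalar contribution in each
#'   condition and their OFF-ON difference
#' @export
contribution_table <- function(circuit, theta, band = c(13, 35),
                               delta = 1e-3) {
  ids <- extrinsic_ids(circuit)
  rows <- lapply(ids, function(id) {
    off <- contribution(circuit, theta, id, "off", band, delta = delta)
    on <- contribution(circuit, theta, id, "on", band, delta = delta)
    data.frame(connection = id, dbeta_dc_off = off$dbeta_dc,
               dbeta_dc_on = on$dbeta_dc,
               difference = off$dbeta_dc - on$dbeta_dc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

stn_connection_ids <- function(circuit) {
  conn <- circuit$connections
  src <- circuit$pops$source
  names(src) <- circuit$pops$id
  ext <- conn$scope == "extrinsic"
  stn <- src[conn$from] == "stn" | src[conn$to] == "stn"
  conn$id[ext & stn]
}

#' Simulated subthalamic lesion
#'
#' Removes the STN from the circuit either by setting every extrinsic
#' connection to and from it to zero gain (`"zero_connections"`) or by
#' deleting the source and its states altogether (`"remove_node"`).  Both
#' modes yield identical spectra for the remaining sources.  Returns the
#' post-lesion spectra and beta summary over the surviving sources.
#'
#' @inheritParams beta_power
#' @param mode `"zero_connections"` or `"remove_node"`
#' @return a `bgdcm_beta` over the non-STN sources, with attribute `mode`
#' @export
lesion_stn <- function(circuit, theta, mode = c("zero_connections",
                                                "remove_node"),
                       condition = c("off", "on"), band = c(13, 35),
                       freq_step = 1) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  if (mode == "zero_connections") {
    theta$gains[stn_connection_ids(circuit)] <- 0
    bp <- beta_power(circuit, theta, condition, band, freq_step)
    keep <- setdiff(names(bp$per_source), "stn")
    out <- structure(list(per_source = bp$per_source[keep],
                          beta = sum(bp$per_source[keep]),
                          freqs = bp$freqs,
                          spectra = bp$spectra[, keep, drop = FALSE],
                          condition = condition), class = "bgdcm_beta")
  } else {
    circ2 <- remove_source(circuit, "stn")
    keep <- circ2$connections$id
    theta2 <- theta
    theta2$gains <- theta$gains[keep]
    theta2$mods <- theta$mods[intersect(names(theta$mods), extrinsic_ids(circ2))]
    theta2$obs <- theta$obs[circ2$observation$channel]
    out <- beta_power(circ2, theta2, condition, band, freq_step)
  }
  attr(out, "mode") <- mode
  out
}

#' Partial lesion: reset one connection to its treated (ON) strength
#'
#' Evaluates beta power for a hybrid parameter set in which a single
#' connection (or several) takes its ON-condition gain while every other
#' connection keeps its OFF-condition strength.  `connection = "all_stn"`
#' resets all four STN-incident connections at once.
#'
#' @param circuit a `bgdcm_circuit`
#' @param theta_off,theta_on condition-resolved parameter sets (see
#'   [condition_theta()]); they must share every non-gain parameter
#' @param connection connection id(s), or `"all_stn"`
#' @param band,freq_step band definition as in [beta_power()]
#' @return a `bgdcm_beta` for the hybrid parameter set
#' @export
partial_lesion <- function(circuit, theta_off, theta_on, connection,
                           band = c(13, 35), freq_step = 1) {
  ids <- if (identical(connection, "all_stn")) stn_connection_ids(circuit)
  else connection
  unknown <- setdiff(ids, circuit$connections$id)
  if (length(unknown))
    stopf("unknown connection(s): %s", paste(unknown, collapse = ", "))
  hybrid <- theta_off
  hybrid$gains[ids] <- theta_on$gains[ids]
  beta_power(circuit, hybrid, condition = "on", band = band,
             freq_step = freq_step)   # gains already condition-resolved
}
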