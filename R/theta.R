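## Parameter sets (theta): synaptic constants, connection gains, condition
## modulators, observation gains and noise-spectrum parameters.  All
## positive quantities are log-parameterised during inversion as deviations
## from the prior mean; a theta object itself stores natural-scale values.

priors_config_path <- function() {
  system.file("extdata", "priors.yaml", package = "bgdcm", mustWork = TRUE)
}

load_priors_config <- function(path = priors_config_path()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$format_version) || cfg$format_version != 1L)
    stopf("incompatible priors config version in %s", path)
  cfg
}

default_gains <- function(cfg = load_priors_config()) {
  unlist(c(cfg$gains$extrinsic, cfg$gains$intrinsic))
}

default_innovation_weights <- function(cfg = load_priors_config()) {
  w <- unlist(cfg$innovation_weights)
  if (is.null(w)) w <- c(ctx.ss = 1, str = 1, gpe = 1, stn = 1, gpi = 1,
                         thal = 1)
  w
}

#' Default parameter set (prior mean) for a circuit
#'
#' Assembles the natural-scale prior-mean parameters: synaptic constants,
#' connection gains, condition modulators (all 1: no condition effect),
#' observation gains and innovation/channel noise-spectrum parameters.
#' Values come from the package's priors configuration
#' (`inst/extdata/priors.yaml`), which documents each entry; they are a
#' reconstruction of conventional steady-state neural-mass priors, tuned
#' once so that the prior-mean circuit is stable and resonates in the beta
#' band, and are not claimed to match any particular archival dataset.
#'
#' @param circuit a `bgdcm_circuit`
#' @param cfg parsed priors configuration (advanced use)
#' @return a list of class `bgdcm_theta` with elements `syn`, `gains`,
#'   `mods`, `obs`, `noise`
#' @export
default_theta <- function(circuit, cfg = load_priors_config()) {
  mods <- rep(1, sum(circuit$connections$scope == "extrinsic"))
  names(mods) <- extrinsic_ids(circuit)
  obs <- unlist(cfg$observation)[circuit$observation$channel]
  gains <- circuit$connections$gain
  names(gains) <- circuit$connections$id
  structure(list(
    syn = do.call(subpop_params, as.list(unlist(cfg$synaptic))),
    gains = gains,
    mods = mods,
    obs = obs,
    noise = unlist(cfg$noise)
  ), class = "bgdcm_theta")
}

#' Condition-specific parameters
#'
#' The two experimental conditions share every parameter except the
#' extrinsic connection gains: the OFF condition multiplies each extrinsic
#' gain by its condition modulator (the OFF/ON gain ratio), so a modulator
#' above one strengthens a connection OFF relative to ON.
#'
#' @param theta a `bgdcm_theta`
#' @param condition `"on"` or `"off"`
#' @return a `bgdcm_theta` with condition-resolved gains and modulators
#'   reset to 1
#' @export
condition_theta <- function(theta, condition = c("on", "off")) {
  condition <- match.arg(condition)
  if (condition == "off") {
    ids <- names(theta$mods)
    theta$gains[ids] <- theta$gains[ids] * theta$mods
  }
  theta$mods[] <- 1
  theta
}

#' @export
print.bgdcm_theta <- function(x, ...) {
  cat("<bgdcm_theta>\n")
  cat("  gains:", paste(sprintf("%s=%.3g", names(x$gains), x$gains),
                        collapse = " "), "\n")
  nm <- names(x$mods)[x$mods != 1]
  if (length(nm))
    cat("  modulated (OFF/ON):",
        paste(sprintf("%s=%.3g", nm, x$mods[nm]), collapse = " "), "\n")
  invisible(x)
}

## --- inversion parameter vector mapping ------------------------------------

## Blocks of the estimable log-deviation vector. Synaptic block covers the
## two rate constants (peak-frequency tuning); amplitudes are absorbed by
## gains and observation scaling.
theta_param_table <- function(circuit, cfg = load_priors_config()) {
  sdv <- unlist(cfg$prior_sd)
  ext <- extrinsic_ids(circuit)
  data.frame(
    name = c(paste0("g.", ext), paste0("m.", ext),
             paste0("obs.", circuit$observation$channel),
             paste0("noise.", names(cfg$noise)),
             "syn.kappa_e", "syn.kappa_i"),
    block = c(rep("gain", length(ext)), rep("mod", length(ext)),
              rep("obs", nrow(circuit$observation)),
              rep("noise", length(cfg$noise)), rep("syn", 2L)),
    sd = c(rep(sdv[["gain"]], length(ext)), rep(sdv[["mod"]], length(ext)),
           rep(sdv[["obs"]], nrow(circuit$observation)),
           rep(sdv[["noise"]], length(cfg$noise)), rep(sdv[["syn"]], 2L)),
    stringsAsFactors = FALSE
  )
}

## Apply a log-deviation vector p (named per theta_param_table) to a
## prior-mean theta.
apply_param_vector <- function(theta, p, circuit) {
  nm <- names(p)
  g <- startsWith(nm, "g.")
  m <- startsWith(nm, "m.")
  o <- startsWith(nm, "obs.")
  n <- startsWith(nm, "noise.")
  theta$gains[sub("^g\\.", "", nm[g])] <-
    theta$gains[sub("^g\\.", "", nm[g])] * exp(p[g])
  theta$mods[sub("^m\\.", "", nm[m])] <-
    theta$mods[sub("^m\\.", "", nm[m])] * exp(p[m])
  theta$obs[sub("^obs\\.", "", nm[o])] <-
    theta$obs[sub("^obs\\.", "", nm[o])] * exp(p[o])
  theta$noise[sub("^noise\\.", "", nm[n])] <-
    theta$noise[sub("^noise\\.", "", nm[n])] * exp(p[n])
  theta$syn[["kappa_e"]] <- theta$syn[["kappa_e"]] * exp(p[["syn.kappa_e"]])
  theta$syn[["kappa_i"]] <- theta$syn[["kappa_i"]] * exp(p[["syn.kappa_i"]])
  theta
}
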