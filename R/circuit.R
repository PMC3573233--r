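## Circuit architectures for the motor cortico-basal-ganglia-thalamocortical
## loop.  Six sources: motor cortex (three-population layered ensemble),
## striatum, external and internal pallidum (GPe, GPi), subthalamic nucleus
## (STN) and motor thalamus.  Subcortical sources are single neural masses,
## glutamatergic (STN, thalamus) or GABAergic (striatum, GPe, GPi).

GLU_KINDS  <- c("spiny_stellate_input", "pyramidal", "excitatory_mass")
GABA_KINDS <- c("inhibitory_interneuron", "inhibitory_mass")

#' Default neural-mass subpopulation parameters
#'
#' Returns the synaptic constants shared by all subpopulations: maximum
#' excitatory/inhibitory postsynaptic amplitudes `He`, `Hi` (mV), synaptic
#' rate constants `kappa_e`, `kappa_i` (1/s, the reciprocals of the 4 ms and
#' 16 ms excitatory/inhibitory membrane kinetics), and the firing-rate
#' sigmoid slope `rho1` (1/mV) and offset `rho2` (mV).  These are the
#' conventional steady-state neural-mass defaults; they can be overridden
#' through the priors configuration (see [default_priors()]).
#'
#' @param He,Hi postsynaptic response amplitudes (mV), positive
#' @param kappa_e,kappa_i synaptic rate constants (1/s), positive
#' @param rho1,rho2 sigmoid slope (1/mV, positive) and offset (mV)
#' @return named numeric vector of the six constants
#' @export
#' @examples
#' subpop_params()
subpop_params <- function(He = 4, Hi = 32, kappa_e = 250, kappa_i = 62.5,
                          rho1 = 2, rho2 = 1) {
  p <- c(He = He, Hi = Hi, kappa_e = kappa_e, kappa_i = kappa_i,
         rho1 = rho1, rho2 = rho2)
  if (any(p[c("He", "Hi", "kappa_e", "kappa_i", "rho1")] <= 0))
    stopf("He, Hi, kappa_e, kappa_i and rho1 must be strictly positive")
  p
}

transmitter_of <- function(kind) {
  ifelse(kind %in% GLU_KINDS, "glutamate", "GABA")
}

make_conn <- function(id, from, to, scope, delay, gain, pops) {
  kind <- pops$kind[match(from, pops$id)]
  sign <- ifelse(transmitter_of(kind) == "glutamate", 1L, -1L)
  data.frame(id = id, from = from, to = to, sign = sign,
             scope = scope, delay = delay, gain = gain,
             stringsAsFactors = FALSE)
}

standard_pops <- function() {
  data.frame(
    id     = c("ctx.ss", "ctx.py", "ctx.ii", "str", "gpe", "stn", "gpi", "thal"),
    source = c("ctx", "ctx", "ctx", "str", "gpe", "stn", "gpi", "thal"),
    kind   = c("spiny_stellate_input", "pyramidal", "inhibitory_interneuron",
               "inhibitory_mass", "inhibitory_mass", "excitatory_mass",
               "inhibitory_mass", "excitatory_mass"),
    stringsAsFactors = FALSE
  )
}

#' Build the standard six-source loop circuit
#'
#' Constructs the standard architecture: cortex projects to striatum and to
#' STN (the hyperdirect pathway); the striatal inhibitory mass projects to
#' GPe (indirect pathway) and GPi (direct pathway); GPe and STN are
#' reciprocally connected; STN excites GPi; GPi inhibits thalamus, which in
#' turn excites cortex.  Cortex is a three-population ensemble (input/spiny
#' stellate, pyramidal, inhibitory interneurons) with the conventional
#' intrinsic wiring; pyramidal cells originate all extrinsic cortical
#' projections and the EEG observation.  Observed channels are cortex, STN
#' and GPi; striatum and thalamus are always hidden.
#'
#' @param params synaptic constants, see [subpop_params()]
#' @param gains optional named numeric vector overriding prior-mean
#'   connection gains (names are connection ids)
#' @param delays named list/vector with elements `extrinsic` and `intrinsic`
#'   (seconds) used as the default conduction delays
#' @return an object of class `bgdcm_circuit`
#' @export
#' @examples
#' circ <- build_standard_circuit()
#' sum(circ$connections$scope == "extrinsic")  # 9
build_standard_circuit <- function(params = subpop_params(),
                                   gains = NULL,
                                   delays = c(extrinsic = 4e-3, intrinsic = 2e-3)) {
  pops <- standard_pops()
  de <- unname(delays["extrinsic"])
  di <- unname(delays["intrinsic"])

  g <- default_gains()
  if (!is.null(gains)) {
    unknown <- setdiff(names(gains), names(g))
    if (length(unknown)) stopf("unknown connection gain(s): %s",
                               paste(unknown, collapse = ", "))
    g[names(gains)] <- gains
  }

  ext <- rbind(
    make_conn("ctx_str",  "ctx.py", "str",  "extrinsic", de, g[["ctx_str"]],  pops),
    make_conn("ctx_stn",  "ctx.py", "stn",  "extrinsic", de, g[["ctx_stn"]],  pops),
    make_conn("str_gpe",  "str",    "gpe",  "extrinsic", de, g[["str_gpe"]],  pops),
    make_conn("str_gpi",  "str",    "gpi",  "extrinsic", de, g[["str_gpi"]],  pops),
    make_conn("gpe_stn",  "gpe",    "stn",  "extrinsic", de, g[["gpe_stn"]],  pops),
    make_conn("stn_gpe",  "stn",    "gpe",  "extrinsic", de, g[["stn_gpe"]],  pops),
    make_conn("stn_gpi",  "stn",    "gpi",  "extrinsic", de, g[["stn_gpi"]],  pops),
    make_conn("gpi_thal", "gpi",    "thal", "extrinsic", de, g[["gpi_thal"]], pops),
    make_conn("thal_ctx", "thal",   "ctx.ss", "extrinsic", de, g[["thal_ctx"]], pops)
  )
  int <- rbind(
    make_conn("ss_py", "ctx.ss", "ctx.py", "intrinsic", di, g[["ss_py"]], pops),
    make_conn("ss_ii", "ctx.ss", "ctx.ii", "intrinsic", di, g[["ss_ii"]], pops),
    make_conn("ii_py", "ctx.ii", "ctx.py", "intrinsic", di, g[["ii_py"]], pops),
    make_conn("py_ss", "ctx.py", "ctx.ss", "intrinsic", di, g[["py_ss"]], pops),
    make_conn("py_ii", "ctx.py", "ctx.ii", "intrinsic", di, g[["py_ii"]], pops)
  )

  structure(list(
    name = "standard",
    sources = c("ctx", "str", "gpe", "stn", "gpi", "thal"),
    pops = pops,
    connections = rbind(ext, int),
    observation = data.frame(channel = c("ctx", "stn", "gpi"),
                             pop = c("ctx.py", "stn", "gpi"),
                             stringsAsFactors = FALSE),
    ## background (unmodelled afferent) activity drives the cortical input
    ## layer and every subcortical mass; an innovation at each node also
    ## anchors the scale of the hidden sources, making the split of a
    ## hidden node's incoming vs outgoing gains identifiable.  Relative
    ## power weights reflect that extrinsic afferent drive converges
    ## mainly on cortex, with quieter direct input to the nuclei.
    innovations = c("ctx.ss", "str", "gpe", "stn", "gpi", "thal"),
    innovation_weights = default_innovation_weights(),
    params = params
  ), class = "bgdcm_circuit")
}

#' Candidate variant architectures
#'
#' Builds one of three alternative architectures evaluated against the
#' standard model: `"gpe_gpi"` adds an inhibitory pallido-pallidal
#' connection from GPe to GPi; `"gpe_striatum"` adds an inhibitory
#' pallido-striatal connection; `"pallidal_channel_to_gpe"` keeps the
#' standard wiring but reassigns the pallidal recording channel to a GPe
#' source (GPi becomes hidden), modelling the possibility that the deep
#' electrode sampled GPe rather than GPi.
#'
#' @param which one of `"gpe_gpi"`, `"gpe_striatum"`,
#'   `"pallidal_channel_to_gpe"`
#' @param ... passed to [build_standard_circuit()]
#' @return a `bgdcm_circuit`
#' @export
build_variant <- function(which = c("gpe_gpi", "gpe_striatum",
                                    "pallidal_channel_to_gpe"), ...) {
  which <- match.arg(which)
  circ <- build_standard_circuit(...)
  de <- circ$connections$delay[circ$connections$scope == "extrinsic"][1]
  g <- default_gains()
  if (which == "gpe_gpi") {
    circ$connections <- rbind(
      circ$connections,
      make_conn("gpe_gpi", "gpe", "gpi", "extrinsic", de, g[["str_gpi"]], circ$pops))
  } else if (which == "gpe_striatum") {
    circ$connections <- rbind(
      circ$connections,
      make_conn("gpe_str", "gpe", "str", "extrinsic", de, g[["str_gpe"]], circ$pops))
  } else {
    circ$observation$pop[circ$observation$channel == "gpi"] <- "gpe"
  }
  circ$name <- which
  ## keep connection row order canonical: extrinsic first
  ord <- order(match(circ$connections$scope, c("extrinsic", "intrinsic")))
  circ$connections <- circ$connections[ord, , drop = FALSE]
  rownames(circ$connections) <- NULL
  circ
}

#' All four candidate architectures
#'
#' @return named list of `bgdcm_circuit` objects: `standard`, `gpe_gpi`,
#'   `gpe_striatum`, `pallidal_channel_to_gpe`
#' @export
candidate_circuits <- function() {
  list(standard = build_standard_circuit(),
       gpe_gpi = build_variant("gpe_gpi"),
       gpe_striatum = build_variant("gpe_striatum"),
       pallidal_channel_to_gpe = build_variant("pallidal_channel_to_gpe"))
}

#' Remove a source from a circuit
#'
#' Deletes the source's subpopulations, every connection incident to them,
#' any observation channel mapped to it and any innovation input it
#' received.  Used by the in-silico lesion analysis.
#'
#' @param circuit a `bgdcm_circuit`
#' @param source source name, e.g. `"stn"`
#' @return a `bgdcm_circuit`
#' @export
remove_source <- function(circuit, source) {
  if (!source %in% circuit$sources) stopf("unknown source '%s'", source)
  drop_pops <- circuit$pops$id[circuit$pops$source == source]
  circuit$sources <- setdiff(circuit$sources, source)
  circuit$pops <- circuit$pops[!circuit$pops$id %in% drop_pops, , drop = FALSE]
  keep <- !(circuit$connections$from %in% drop_pops |
              circuit$connections$to %in% drop_pops)
  circuit$connections <- circuit$connections[keep, , drop = FALSE]
  circuit$observation <- circuit$observation[
    !circuit$observation$pop %in% drop_pops, , drop = FALSE]
  circuit$innovations <- setdiff(circuit$innovations, drop_pops)
  if (!is.null(circuit$innovation_weights))
    circuit$innovation_weights <-
      circuit$innovation_weights[circuit$innovations]
  rownames(circuit$pops) <- rownames(circuit$connections) <- NULL
  circuit
}

extrinsic_ids <- function(circuit) {
  circuit$connections$id[circuit$connections$scope == "extrinsic"]
}

hidden_sources <- function(circuit) {
  obs_src <- circuit$pops$source[match(circuit$observation$pop, circuit$pops$id)]
  setdiff(circuit$sources, obs_src)
}

#' Sigmoid firing-rate function
#'
#' Centred logistic mapping from mean depolarisation (mV, deviation from
#' baseline) to normalised ensemble firing-rate deviation: zero input maps
#' to zero output, and the output saturates for large depolarisation.
#'
#' @param v depolarisation (mV), vectorised
#' @param params synaptic constants ([subpop_params()]); only `rho1`,
#'   `rho2` are used
#' @return firing-rate deviation, same length as `v`
#' @export
sigmoid_firing <- function(v, params = subpop_params()) {
  r1 <- params[["rho1"]]; r2 <- params[["rho2"]]
  1 / (1 + exp(-r1 * (v - r2))) - 1 / (1 + exp(r1 * r2))
}

sigmoid_slope <- function(v, params) {
  r1 <- params[["rho1"]]; r2 <- params[["rho2"]]
  e <- exp(-r1 * (v - r2))
  r1 * e / (1 + e)^2
}

#' @export
print.bgdcm_circuit <- function(x, ...) {
  cat(sprintf("<bgdcm_circuit '%s'>\n", x$name))
  cat(sprintf("  sources: %s\n", paste(x$sources, collapse = ", ")))
  cat(sprintf("  subpopulations: %d   states: %d\n", nrow(x$pops), 4L * nrow(x$pops)))
  ne <- sum(x$connections$scope == "extrinsic")
  cat(sprintf("  connections: %d extrinsic, %d intrinsic\n",
              ne, nrow(x$connections) - ne))
  cat(sprintf("  observed: %s   hidden: %s\n",
              paste(x$observation$channel, collapse = ", "),
              paste(hidden_sources(x), collapse = ", ")))
  invisible(x)
}

#' Serialize / deserialize a circuit to JSON
#'
#' Round-trips sources, subpopulations, connections (from, to, sign, gain,
#' delay, scope), the observation map and innovation sites losslessly.
#'
#' @param circuit a `bgdcm_circuit`
#' @param path file path
#' @return `circuit_from_json` returns a `bgdcm_circuit`
#' @export
circuit_to_json <- function(circuit, path) {
  obj <- unclass(circuit)
  obj$params <- as.list(obj$params)           # keep names through JSON
  obj$innovation_weights <- as.list(obj$innovation_weights)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname circuit_to_json
#' @export
circuit_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stopf("incompatible circuit file version")
  obj$format_version <- NULL
  obj$pops <- as.data.frame(obj$pops, stringsAsFactors = FALSE)
  obj$connections <- as.data.frame(obj$connections, stringsAsFactors = FALSE)
  obj$observation <- as.data.frame(obj$observation, stringsAsFactors = FALSE)
  obj$params <- unlist(obj$params)
  obj$innovation_weights <- unlist(obj$innovation_weights)
  structure(obj, class = "bgdcm_circuit")
}

#' Directed path search between sources
#'
#' Tests whether an ordered sequence of sources forms a directed walk along
#' extrinsic connections (used to verify the direct, indirect and
#' hyperdirect pathways are wired).
#'
#' @param circuit a `bgdcm_circuit`
#' @param sources character vector of source names in walk order
#' @return logical
#' @export
has_pathway <- function(circuit, sources) {
  conn <- circuit$connections[circuit$connections$scope == "extrinsic", ]
  src_of <- function(pop) circuit$pops$source[match(pop, circuit$pops$id)]
  edges <- cbind(src_of(conn$from), src_of(conn$to))
  for (i in seq_len(length(sources) - 1L)) {
    hit <- edges[, 1] == sources[i] & edges[, 2] == sources[i + 1L]
    if (!any(hit)) return(FALSE)
  }
  TRUE
}
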