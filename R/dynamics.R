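## Neural-mass dynamics.  Each subpopulation carries two synaptic channels
## (excitatory, inhibitory); each channel is a critically damped
## second-order (alpha-kernel) system
##    v' = z,   z' = kappa * H * input - 2 kappa z - kappa^2 v
## whose impulse response is H * kappa * t * exp(-kappa t).  The
## subpopulation's depolarisation is v_e - v_i; its firing-rate deviation
## is the centred sigmoid of that depolarisation.

state_index <- function(circuit) {
  npop <- nrow(circuit$pops)
  base <- 4L * (seq_len(npop) - 1L)
  list(npop = npop, nx = 4L * npop,
       ve = base + 1L, ze = base + 2L, vi = base + 3L, zi = base + 4L)
}

pop_depolarisation <- function(x, idx) x[idx$ve] - x[idx$vi]

## Assemble per-channel synaptic input given presynaptic firing `s`
## (vector over subpopulations) and exogenous input `u` (vector over
## subpopulations, enters the excitatory channel).
synaptic_input <- function(s, u, circuit) {
  conn <- circuit$connections
  pid <- circuit$pops$id
  exc <- inh <- numeric(length(pid))
  from_i <- match(conn$from, pid)
  to_i <- match(conn$to, pid)
  drive <- conn$gain * s[from_i]
  for (k in seq_len(nrow(conn))) {
    if (conn$sign[k] > 0) exc[to_i[k]] <- exc[to_i[k]] + drive[k]
    else inh[to_i[k]] <- inh[to_i[k]] + drive[k]
  }
  list(exc = exc + u, inh = inh)
}

#' Time derivative of the full state vector
#'
#' Evaluates the neural-mass vector field at state `x` with exogenous input
#' `u`.  Conduction delays do not enter this time-domain evaluation (they
#' are handled exactly, as phase factors, in the spectral domain after
#' linearisation); the delayed-input simulator [simulate_states()] applies
#' them with lag buffers.
#'
#' @param x state vector, length `4 * n_subpopulations`, ordered
#'   `(v_e, z_e, v_i, z_i)` per subpopulation
#' @param u exogenous input: scalar, or vector over subpopulations (mV/s
#'   equivalents entering the excitatory channel)
#' @param circuit a `bgdcm_circuit`
#' @param theta a `bgdcm_theta`
#' @return dx/dt, same length as `x`
#' @export
state_derivative <- function(x, u, circuit, theta) {
  idx <- state_index(circuit)
  if (length(x) != idx$nx)
    stopf("state vector has length %d, expected %d", length(x), idx$nx)
  if (length(u) == 1L) u <- rep(u, idx$npop)
  if (length(u) != idx$npop)
    stopf("input vector has length %d, expected 1 or %d", length(u), idx$npop)
  syn <- theta$syn
  circuit$connections$gain <- theta$gains[circuit$connections$id]
  s <- sigmoid_firing(pop_depolarisation(x, idx), syn)
  inp <- synaptic_input(s, u, circuit)
  dx <- numeric(idx$nx)
  ke <- syn[["kappa_e"]]; ki <- syn[["kappa_i"]]
  dx[idx$ve] <- x[idx$ze]
  dx[idx$vi] <- x[idx$zi]
  dx[idx$ze] <- ke * syn[["He"]] * inp$exc - 2 * ke * x[idx$ze] - ke^2 * x[idx$ve]
  dx[idx$zi] <- ki * syn[["Hi"]] * inp$inh - 2 * ki * x[idx$zi] - ki^2 * x[idx$vi]
  dx
}

#' Fixed point of the deterministic dynamics
#'
#' Newton iteration for the equilibrium of the vector field under constant
#' input `u0`.  With the centred sigmoid and zero input the origin is an
#' exact fixed point; nonzero input or an off-centre parameterisation is
#' handled by damped Newton steps with the (zero-delay aggregate) Jacobian.
#'
#' @inheritParams state_derivative
#' @param u0 constant exogenous input (default 0)
#' @param tol residual norm tolerance (state units)
#' @param max_iter iteration cap
#' @return the fixed-point state vector `x0`
#' @export
find_fixed_point <- function(circuit, theta, u0 = 0, tol = 1e-8,
                             max_iter = 50L) {
  idx <- state_index(circuit)
  x <- numeric(idx$nx)
  for (it in seq_len(max_iter)) {
    fx <- state_derivative(x, u0, circuit, theta)
    if (sqrt(sum(fx^2)) < tol) return(x)
    A <- aggregate_jacobian(circuit, theta, x)
    step <- tryCatch(solve(A, fx), error = function(e) NULL)
    if (is.null(step)) stopf("singular Jacobian in fixed-point search")
    x <- x - step
  }
  fx <- state_derivative(x, u0, circuit, theta)
  if (sqrt(sum(fx^2)) < tol) return(x)
  stopf("fixed-point search did not converge (unstable parameterisation?)")
}

#' Simulate the linearised stochastic dynamics (stochastic Heun)
#'
#' Integrates the delay linear stochastic system obtained by linearising
#' the circuit at its fixed point, driven by the innovation processes of
#' `theta$noise` (white plus 1/f, generated spectrally and fed through the
#' input matrix).  The drift uses a Heun (predictor-corrector) step, which
#' avoids the damping bias a plain forward-Euler step leaves in resonance
#' peaks; delays are applied through per-block lag buffers rounded to the
#' integration step.  This is the slow, independent route to realisations;
#' [simulate_recording()] uses fast spectral synthesis by default.
#'
#' @inheritParams state_derivative
#' @param duration seconds
#' @param fs output sampling rate (Hz)
#' @param dt integration step (s); must divide 1/fs
#' @param seed integer seed
#' @return matrix `nx x (duration*fs)` of states at the output rate
#' @export
simulate_states <- function(circuit, theta, duration = 10, fs = 1000,
                            dt = 2.5e-4, seed = 1L) {
  ss <- linearize(circuit, theta)
  nkeep <- round(1 / (fs * dt))
  if (abs(nkeep - 1 / (fs * dt)) > 1e-9) stopf("dt must divide 1/fs")
  nsteps <- round(duration * fs) * nkeep
  nx <- nrow(ss$A[[1]])
  nin <- ncol(ss$B)
  set.seed(seed)
  ## innovation series at the integration rate: unit-PSD white + 1/f shaped,
  ## scaled so the continuous-time input PSD matches innovation_spectrum().
  innov <- matrix(0, nin, nsteps)
  for (j in seq_len(nin)) {
    innov[j, ] <- synth_noise_series(nsteps, 1 / dt, theta$noise[["u_white"]],
                                     theta$noise[["u_pink"]])
  }
  Ac <- array(unlist(ss$A, use.names = FALSE), c(nx, nx, length(ss$A)))
  euler_sim_cpp(Ac, ss$delays, ss$B, innov, dt, nkeep)
}
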