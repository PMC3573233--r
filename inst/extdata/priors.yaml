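# Prior (default) parameter values for the six-source loop model.
# These are a reconstruction of conventional steady-state neural-mass
# defaults (4 ms / 16 ms excitatory/inhibitory kinetics, centred logistic
# firing curve), with connection gains chosen once so that the prior-mean
# circuit is stable and the strengthened (OFF) configuration resonates in
# the beta band.  They are package defaults, not values copied from any
# particular archival dataset.
format_version: 1
synaptic:
  He: 4          # mV, max excitatory postsynaptic amplitude
  Hi: 32         # mV, max inhibitory postsynaptic amplitude
  kappa_e: 250   # 1/s (tau_e = 4 ms)
  kappa_i: 110   # 1/s (tau_i ~ 9 ms; places loop resonances in the beta band)
  rho1: 2        # 1/mV, sigmoid slope
  rho2: 1        # mV, sigmoid offset
delays:
  extrinsic: 0.004   # s
  intrinsic: 0.002   # s
gains:
  extrinsic:
    ctx_str: 10.0
    ctx_stn: 100.0   # hyperdirect pathway: a principal driver of STN beta
    str_gpe: 10.0
    str_gpi: 20.0
    gpe_stn: 70.0
    stn_gpe: 70.0
    stn_gpi: 20.0
    gpi_thal: 80.0
    thal_ctx: 80.0
  intrinsic:
    ss_py: 150.0
    ss_ii: 30.0
    ii_py: 100.0
    py_ii: 100.0
    py_ss: 4.0
innovation_weights:  # relative background-input power per node; afferent
  ctx.ss: 1.0        # drive converges mainly on cortex
  str: 0.1
  gpe: 0.1
  stn: 0.1
  gpi: 0.1
  thal: 0.1
observation:
  ctx: 1.0
  stn: 1.0
  gpi: 1.0
noise:
  u_white: 1.0    # innovation white amplitude (power units)
  u_pink: 1.0     # innovation 1/f amplitude at 1 Hz
  c_white: 2.0e-6 # channel noise white amplitude (a few % of signal power)
  c_pink: 2.0e-5  # channel noise 1/f amplitude at 1 Hz
prior_sd:        # log-deviation prior SDs per parameter block
  gain: 0.25
  mod: 0.25
  obs: 0.5
  noise: 0.5
  syn: 0.1
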