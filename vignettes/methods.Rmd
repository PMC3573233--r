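---
title: "Modelling beta-band interactions in the cortico-basal-ganglia-thalamocortical loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling beta-band interactions in the cortico-basal-ganglia-thalamocortical loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgdcm)
```

# The scientific problem

Untreated Parkinsonism is accompanied by exaggerated oscillations in the
beta band (13--35 Hz) throughout the motor cortico--basal-ganglia--
thalamocortical loop, and dopaminergic treatment attenuates them.  Only a
few nodes of that loop can be recorded in patients -- typically one scalp
EEG channel over motor cortex and deep-brain-stimulation electrodes in the
subthalamic nucleus (STN) and internal pallidum (GPi).  `bgdcm` implements
a generative-model approach to this setting: a neural-mass model of the
whole six-source loop predicts the auto- and cross-spectral densities of
the recorded channels, and Bayesian inversion of that model infers the
directed (effective) connection strengths -- including those of hidden
sources -- together with how they change between the treated (ON) and
untreated (OFF) states.

# The generative model

## Circuit

Six sources: motor cortex, striatum, external pallidum (GPe), STN, GPi and
motor thalamus.  Cortex is a three-population layered ensemble (input/spiny
stellate cells, pyramidal projection cells, inhibitory interneurons); each
subcortical source is a single neural mass, glutamatergic (STN, thalamus)
or GABAergic (striatum, GPe, GPi).  The standard architecture carries nine
extrinsic connections: the hyperdirect pathway (cortex to STN), the direct
pathway (cortex to striatum to GPi), the indirect pathway (cortex to
striatum to GPe to STN to GPi), the reciprocal GPe--STN loop, and the
return path GPi to thalamus to cortex.  Candidate alternatives add a
pallido-pallidal (GPe to GPi) or pallido-striatal (GPe to striatum)
connection, or re-assign the pallidal recording channel to a GPe source;
`candidate_circuits()` returns all four.

## Dynamics

Each subpopulation carries an excitatory and an inhibitory synaptic
channel.  A channel is a critically damped second-order system ("alpha
kernel"): `v' = z`, `z' = kappa H u - 2 kappa z - kappa^2 v`, with impulse
response `H kappa t exp(-kappa t)`.  Presynaptic influence is the centred
sigmoid of the presynaptic depolarisation, scaled by a non-negative
connection gain; glutamatergic afferents drive the excitatory channel,
GABAergic afferents the inhibitory one, and the subpopulation
depolarisation is their difference.  Because the sigmoid is centred, the
origin is an exact fixed point of the unforced system, and the model used
for spectra is the linearisation there.  Conduction delays do not enter
the time-domain equations; after linearisation they are applied exactly as
per-delay phase factors `exp(-i w delta)` on the corresponding Jacobian
blocks, so steady-state predictions carry no delay-approximation error.

## Spectral observation model

Stationary fluctuations are driven by white plus 1/f "innovation"
processes entering the cortical input layer and every subcortical mass.
An innovation at each node is more than realism: it anchors the activity
scale of the hidden sources.  Without it, scaling a hidden node's incoming
gains up and its outgoing gains down leaves every observable spectrum
unchanged, and quantities like the split of the GPe--STN loop gain between
its two legs would be unidentifiable.  Relative innovation power is
weighted per node (cortex 1, nuclei 0.1 by default), reflecting that
extrinsic afferent drive converges mainly on cortex; with these weights
the cortically driven share of STN beta power is appreciable, which is
what makes hyperdirect-pathway changes detectable from spectra at
realistic segment lengths.

The predicted channel cross-spectral matrix is
`S(w) = T(w) G_u(w) T(w)* + G_c(w) I`, where
`T(w) = C (iwI - sum_d A_d e^{-iw delta_d})^{-1} B` and `G_c` is a white +
1/f measurement-noise spectrum.  `S(w)` is Hermitian positive semidefinite
by construction; the test suite asserts this property over random
parameter draws rather than projecting onto it.

## Default parameters

The synaptic constants are conventional neural-mass values: `He = 4` mV,
`Hi = 32` mV, `kappa_e = 250` 1/s (4 ms), sigmoid slope 2 /mV and offset
1 mV.  The inhibitory rate constant default is `kappa_i = 110` 1/s
(~9 ms), which places the resonance of excitatory--inhibitory loop pairs
(cortical pyramidal--interneuron, and STN--GPe with its conduction delays)
at 15--20 Hz.  Connection-gain defaults were chosen once so that (i) the
prior-mean circuit is stable with a comfortable margin, (ii) the untreated
(OFF) configuration -- hyperdirect, pallido-subthalamic and
subthalamo-pallidal gains scaled by 1.5 -- shows a clear beta peak in every
channel with STN most affected, and (iii) the hyperdirect pathway is a
material driver of subthalamic beta, consistent with its central role in
current accounts of Parkinsonian beta.  All defaults live in
`inst/extdata/priors.yaml`; they are this package's reconstruction of a
plausible prior regime, not values copied from any archival dataset, and
every one of them can be overridden.

```{r}
circ <- build_standard_circuit()
circ
```

# Data features

Raw segments (1 kHz; one cortical EEG channel, three bipolar contacts per
deep site) are reduced exactly the way the analysis pipeline expects
patient data to be reduced:

1. **First principal component** per deep site (SVD of the centred 3 x T
   contact matrix), sign-fixed so the largest loading is positive.
2. **Anti-alias filtering and decimation** to ~125 Hz.  An order-8
   autoregression at 1 kHz would have an 8 ms regression window and could
   not represent a 20 Hz resonance; after decimation the beta band
   occupies a healthy fraction of the Nyquist range and the order-8 model
   has four pole pairs for at most four spectral peaks.
3. **Shrinkage VAR(8)**: ridge (zero-mean Gaussian prior) conditional-mean
   estimates of the coefficient matrices on per-channel standardised
   series, innovation covariance from the residuals.
4. **Spectral transform** `S(w) = H(w) E H(w)*` with
   `H(w) = (I - sum_k A_k e^{-iwk/fs})^{-1}`, evaluated on the 13--35 Hz
   grid.  The normalisation follows the white-noise identity (zero
   coefficients give `S = E`).  Note the leading identity in `H`: writing
   the transform without it does not yield a valid spectral factorisation.

The model order is fixed at 8 by default.  Higher orders can split a
single spectral peak in two (a recognised failure mode of autoregressive
spectra); the test suite carries a diagnostic case at order 14.

# Inversion

A paired OFF/ON segment is fitted jointly.  All parameters are shared
between the conditions except one multiplicative **condition modulator**
per extrinsic connection (the OFF/ON gain ratio, log-parameterised, prior
centred at ratio 1 with SD 0.25 log units).  The estimable vector further
contains log-deviations of the extrinsic gains (SD 0.25), observation
gains (SD 0.5), noise-spectrum amplitudes (SD 0.5) and the two synaptic
rate constants (SD 0.1); 27 parameters for the standard architecture.

The likelihood treats the real and imaginary parts of the upper-triangle
cross-spectral entries (and the real auto-spectra) as Gaussian features.
Three devices matter in practice:

* **Per-channel-pair weighting.**  Each feature series is normalised by
  the geometric mean of its two channels' band-average auto power, so the
  strongest spectrum does not monopolise a shared precision.
* **Operator-consistent prediction.**  The data features are VAR(8)
  spectra of filtered, decimated series -- not raw spectra.  Predictions
  are therefore pushed through the same operator: the model CSD is
  evaluated on a full grid up to the decimated Nyquist rate, multiplied by
  the decimation filter's exact power response, reduced to the population
  VAR(8) via the Yule--Walker equations, and only then compared with the
  data.  Without this step the deliberate smoothing of the order-8 model
  masquerades as condition effects and biases the modulators.
* **Likelihood tempering.**  The 414 band features are smooth functions of
  ~156 underlying VAR quantities, so the feature precision is scaled by
  that ratio.  Without tempering, per-segment credible intervals are too
  narrow and the group criteria flag spurious connections.

Optimisation is Gauss--Newton ascent on the variational (Laplace) free
energy with Levenberg--Marquardt regularisation, step rejection whenever
the free energy would decrease, a damped fixed-point update of the noise
precision, convergence after three successive accepted steps improving by
less than 0.01 nats, and a cap of 128 iterations.  The free energy is
accuracy minus complexity, the complexity being the Gaussian KL divergence
from posterior to prior; differences of free energies are log Bayes
factors, and fixed-effects group comparison sums free energies over
segment pairs.

The overall data scale is arbitrary (recording gains are unknown), so the
data are rescaled once to match the prior-mean prediction's band-average
auto power before fitting; the factor is recorded in the posterior object.

# Group inference

Following the simple-averaging convention, group means of log modulators
are arithmetic means of the per-segment conditional means, and the group
95% interval is the mean of the per-segment interval bounds (a
precision-weighted alternative is available behind a flag).  A connection
is flagged as increased (decreased) OFF relative to ON only if (i) the
group-pooled posterior places more than 95% of its mass on that side of
ratio 1 and (ii) at least 50% of segment pairs individually exclude ratio
1 in the same direction -- the inclusive reading of "at least half".
Poorly fitting pairs are screened out beforehand by a robust rule (free
energy more than 3 scaled MADs below the cohort median); the criterion is
configurable since no exact rule is canonical.

The Wilcoxon signed-rank test used by the contribution and lesion analyses
drops zero differences, uses mid-ranks for ties and computes the exact
two-sided p-value for up to 25 non-zero pairs from the full null
distribution of the statistic (a generating-function recursion equivalent
to enumerating all 2^n sign assignments, and verified against that
enumeration in the tests); larger samples use the tie-corrected normal
approximation.

# Contribution and lesion analyses

`beta_power()` integrates the innovation-driven depolarisation spectrum of
every source's principal population over 13--35 Hz -- hidden sources
included, through the same transfer machinery as the observed channels --
and sums them into a network beta score.  `contribution()` differentiates
that score with respect to one connection gain by central finite
differences at a relative step of 1e-3 (small steps probe the operating
circuit without reconfiguring it; the step shrinks once by 10x if a
stencil point is unstable, then fails).  Source averaging is unweighted.

`lesion_stn()` removes the STN either by zeroing all four of its extrinsic
connections or by deleting the source and its states; the two must agree
to within numerical precision for the surviving sources' spectra, in all
four architectures -- a structural identity the tests assert.
`partial_lesion()` instead resets chosen connections to their ON-state
gains while the rest of the circuit keeps its OFF strengths.

# The synthetic cohort generator

`make_ground_truth()` emulates the study layout the pipeline is designed
for: 5 subjects, 3 segment pairs per condition, ~50 s segments at 1 kHz,
one EEG channel and three bipolar contacts per deep site.  Per subject,
extrinsic gains are jittered log-normally (SD 0.1) around the prior mean;
per segment pair a smaller shared jitter (SD 0.05) is applied, and the OFF
member multiplies the hyperdirect, pallido-subthalamic and
subthalamo-pallidal gains by 1.5 -- so the OFF/ON ratio is exact ground
truth for every pair.  Unstable draws are rejected and redrawn (at most
10 times).  The effect size 1.5 gives comfortable identifiability at 50 s
segments and is configurable for power analyses.

`simulate_recording()` synthesises recordings from the linearised
stochastic circuit: by default in the frequency domain from the exact
transfer functions (evaluated exactly on the synthesis grid below 100 Hz,
where the resonances live), or by Euler--Maruyama integration of the delay
stochastic system (`method = "euler"`), which serves as the independent
oracle for the spectral route in the tests.  Deep sources are mixed onto
their three contacts with loadings (1.0, 0.7, 0.4) plus independent sensor
noise at 10% of each contact's projected source variance; cortex gets the
same relative sensor noise.

What the generator does **not** emulate: volume conduction and electrode
geometry, artefacts and line noise, non-stationarity within segments,
between-subject differences in synaptic constants, and any nonlinear
(large-amplitude) dynamics -- the data are realisations of the linearised
model.  Passing recovery tests on these cohorts therefore demonstrates
that the pipeline is correct and well calibrated under the model's own
assumptions at realistic sizes and noise levels; it cannot certify
performance on real patient recordings.

# Numerical choices and problem sizes

* Inversion grid: 13--35 Hz at 1 Hz; operator-consistent reduction grid:
  0 to 62.5 Hz at 0.5 Hz.
* Fixed points by damped Newton iteration (tolerance 1e-8 in state units);
  with centred sigmoids and zero input the origin is exact.
* Stability is monitored through the real parts of the zero-delay
  aggregate Jacobian's eigenvalues; unstable parameterisations raise
  errors rather than returning silently wrong spectra.
* Jacobians of the feature prediction by one-sided finite differences
  (step 1e-3 log units); modulator columns only re-evaluate the OFF
  condition.
* The hot loops (frequency-response stacks, Euler--Maruyama stepping) are
  compiled (RcppArmadillo); the plain-R `transfer_matrix()` is retained
  and the two are cross-checked in the tests.
* Parameter-recovery experiments in the tests and the acceptance script
  use the generator defaults (5 subjects x 3 pairs x 50 s); the
  model-recovery comparison uses one subject's three pairs across the
  four architectures, which already separates the models by hundreds of
  nats.

# Known limitations

* The thalamic relay is constrained only through its influence on cortex;
  with no recorded thalamic channel the pallido-thalamic and
  thalamo-cortical gains are nearly exchangeable, and their individual
  posteriors should not be over-interpreted (their product is the
  identified quantity).
* The exclusion rule for poor fits, the feature-noise model and the
  likelihood tempering are pragmatic, documented choices; none is claimed
  to be uniquely correct.
* Only extrinsic gains may differ between conditions.  Treatment effects
  expressed through synaptic (intrinsic) parameters would be absorbed,
  imperfectly, into gain changes.
* The generator and the inversion share the same forward model, which is
  the point of a recovery study but also its limit: feature-pipeline
  distortions are modelled (filter response, VAR reduction), yet any
  real-data mismatch of the neural-mass form itself is outside what these
  tests can detect.
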