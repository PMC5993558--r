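---
title: "Modeling subthalamic deep brain stimulation in a corticothalamic-basal ganglia neural field"
author: "ctbgsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling subthalamic deep brain stimulation in a corticothalamic-basal ganglia neural field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ctbgsim` simulates a mean-field (neural field) description of the
corticothalamic-basal ganglia (CTBG) circuit: nine interacting neural
populations whose state variables are population-mean soma potentials
$V_a(t)$ and mean firing-rate fields $\phi_a(t)$.  The populations are
cortical pyramidal neurons ($e$) and inhibitory interneurons ($i$), thalamic
specific relay nuclei ($s$) and reticular nucleus ($r$), striatal D1- and
D2-receptor populations ($d_1$, $d_2$), the internal and external globus
pallidus ($p_1$, $p_2$), and the subthalamic nucleus (STN, $\zeta$; label
`"z"` in code).  An external channel $n$ delivers a constant drive
$\phi_n$ to the relay nuclei, and a stimulation channel $x$ models deep
brain stimulation (DBS).

Three standard neural-field ingredients define the dynamics.

1. **Firing response.**  Each population converts potential to rate through
   a sigmoid
   $$Q_a = S_a(V_a) = \frac{Q_a^{\max}}{1 + \exp[-(V_a - \theta_a)/\sigma']},$$
   with maximum rate $Q_a^{\max}$, threshold $\theta_a$, and a spread
   $\sigma'$ shared by all populations.  $\sigma'$ enters the exponential
   directly, in mV.

2. **Axonal propagation.**  Only cortical pyramidal axons are long enough
   for wave propagation to matter; their rate field obeys the damped wave
   equation, which in the spatially uniform mode reduces to
   $$\frac{1}{\gamma_e^2}\ddot{\phi_e} + \frac{2}{\gamma_e}\dot{\phi_e} +
     \phi_e = Q_e .$$
   Every other population (including the interneurons) uses the
   local-interaction approximation $\phi_a = Q_a$.  Because intracortical
   connectivity is random (synapse numbers proportional to neuron numbers),
   $V_i = V_e$ and $Q_i = Q_e$: the interneurons are represented through the
   cortical state and carry no independent variables.  In the dynamical
   equations the $\nu_{ei}$ term therefore reads the instantaneous cortical
   rate $Q_e$, not the propagating field $\phi_e$ — the two coincide only at
   steady state.

3. **Synaptodendritic response.**  Afferent rate is converted to
   postsynaptic potential by a second-order low-pass operator with decay
   rate $\alpha$ and rise rate $\beta$,
   $$\frac{1}{\alpha\beta}\ddot V_a + \Big(\frac{1}{\alpha} +
     \frac{1}{\beta}\Big)\dot V_a + V_a =
     \sum_b \nu_{ab}\,\phi_b(t - \tau_{ab}),$$
   where $\nu_{ab}$ (mV s) is the connection strength and $\tau_{ab}$ the
   axonal delay.  Since a single $(\alpha, \beta)$ pair applies to every
   connection, the per-connection potentials can be summed before
   filtering; this reduces the state to 18 variables (two per modeled
   population plus two for the cortical wave), and the equivalence with
   per-connection filtering is verified in the test suite against an
   independent `deSolve` integration.

The packaged defaults (also shipped as
`inst/extdata/parkinsonian.yaml`) are a nominal parkinsonian parameter
set: an overstrong STN$\to$GPe coupling ($\nu_{p_2\zeta} = 2.4$ mV s) and
cortico-subthalamic coupling ($\nu_{\zeta e} = 1.3$ mV s) create a
pathologically strong subthalamo-pallidal loop and hyperdirect pathway.
The only nonzero delays are corticothalamic: $\tau_{re} = \tau_{se} =
45$ ms and $\tau_{es} = 35$ ms; all intra-basal-ganglia and
cortex-to-basal-ganglia delays are zero, the synaptic low-pass providing
the loop lag.

## Steady states and gains

Setting all derivatives to zero and eliminating the dependent populations
($\phi_\zeta$ from $(\phi_e, \phi_{p_2})$, then $\phi_{p_1}$, then
$\phi_r$) reduces the fixed-point problem to five simultaneous equations
in $(\phi_e, \phi_s, \phi_{d_1}, \phi_{d_2}, \phi_{p_2})$
(`reduced_residuals()`).  `solve_steady_states()` enumerates roots by
damped Newton iteration from (i) deterministic Halton low-discrepancy
starts, (ii) the lowest-residual points of a coarse pre-scan, and (iii) a
structured one-dimensional continuation walk in $\phi_e$ that brackets sign
changes of the relay residual along each pallidal solution branch.  The
parkinsonian set has two interior fixed points; a brute-force grid oracle
in the test suite confirms that sign-change cells of the residual field and
reported roots match one-to-one.  Residuals are computed in rate units;
convergence is declared on the potential-equivalent residual (rate residual
divided by the local sigmoid slope) at a default tolerance of
$10^{-12}$ mV, with a rate-space cap of $10^{-9}\,\mathrm{s}^{-1}$ where
the slope vanishes.  Simulations start from the **low-firing operating
state** (smallest $\phi_e$, ties broken by $\phi_s$;
`select_operating_state()`).

Linearizing the sigmoid at a fixed point gives the population slopes
$\rho_a = \phi_a^{(0)}(1 - \phi_a^{(0)}/Q_a^{\max})/\sigma'$ and the
connection gains $G_{ab} = \rho_a \nu_{ab}$ (`gains()`), whose products
along closed paths (`loop_gain()`, `ctbg_loops()`) quantify the STN-GPe,
hyperdirect, direct and indirect loops.

## The operating regime and the role of noise

At the nominal parameters the low-firing fixed point is a **marginally
stable focus**: its least-damped mode decays at roughly $1\,$s$^{-1}$ while
rotating at $2\pi \times 26$ Hz, and the Hopf bifurcation of the STN-GPe
resonance lies within about 0.1% of the nominal STN$\to$GPe coupling
(increase $\nu_{p_2\zeta}$ by $\sim$0.003 mV s and the focus becomes a
limit cycle).  A noise-free simulation from the operating state therefore
decays to equilibrium and has an empty spectrum.

The package treats this the way driven neural-field models are normally
analysed: the constant external drive $\phi_n$ carries an optional
white-noise component (`noise` argument of `simulate_ctbg()`),
parameterized by its one-sided spectral density so that the forcing is
independent of the integration step.  The packaged study conditions
(`study_conditions()`) use a density of $0.1\,\mathrm{s^{-2}\,Hz^{-1}}$,
chosen once so that the excited STN oscillation is large (peak-to-peak
swings comparable to its mean rate, as expected of a pathological rhythm)
and its nonlinear second harmonic is clearly resolved; the seed is a
first-class input recorded in all outputs.

What this regime does and does not establish:

* **Robust:** the resonance frequencies (the $\sim$26 Hz beta line, its
  $\sim$52 Hz harmonic, and the $\sim$6 Hz corticothalamic tremor-band
  peak) are properties of the linearized loop structure and are insensitive
  to the noise amplitude; power *ratios* between stimulated and
  unstimulated runs are likewise amplitude-independent in the near-linear
  regime.
* **Regime-dependent:** threshold-like observables — the pulse frequency at
  which beta power first drops a fixed factor, and the width of the 1:1
  entrainment range — depend on how far the system sits from the Hopf
  point.  On the stable side, beta power responds steeply to any effective
  mean perturbation (two orders of magnitude already at the 100 Hz end of
  the scan), and the resonantly amplified stimulus line dominates the
  spectrum throughout a 24-28 Hz scan.  A deeply supercritical limit cycle
  would instead resist small perturbations up to a sharper threshold and
  lock only in a narrow Arnold tongue.  Within a fraction of a percent of the
  nominal couplings no parameterization reaches that deep regime, so the
  packaged conditions stay on the faithful, marginally stable side and the
  threshold/locking readouts should be interpreted accordingly.

## Modeling DBS

Stimulation is an external pulse rate: a periodic train of top-hat pulses
of amplitude $\phi_x^{\max}$, width $t_{\text{width}}$ and frequency
$f_{\text{stim}}$ (`stim_protocol()`), coupled like any other afferent
through the dendritic filter with zero delay.  It reaches the STN with a
negative coupling ($\nu_{\zeta x} = -1.2$ mV s; the population-mean effect
of axonal activation is inhibitory there) and both pallidal segments with
positive couplings ($\nu_{p_1 x} = \nu_{p_2 x} = 1.2$ mV s; activation of
afferent terminals near the electrode).  The default pulse width of 0.7 ms
leaves the $\sim$7 ms inter-pulse quiescent period characteristic of
clinical 130 Hz stimulation.

Because the dendritic response (time constants $1/\beta = 5$ ms to
$1/\alpha = 20$ ms) is slower than the inter-pulse interval at clinical
frequencies, the evoked potential is a small ripple about a constant mean
$\nu_{ax}\phi_x^{\max} t_{\text{width}} f_{\text{stim}}$
(`mean_perturbation()`); `apply_direct_perturbation()` applies that mean
directly, and the `direct-vs-indirect` preset verifies that both routes
suppress beta power identically.  Its default sign convention inhibits the
STN and excites the pallidum, matching the DBS coupling signs; the
opposite pattern is available as `convention = "reversed"`.

The pulse amplitude is the one free quantity the model does not print.
`calibrate_amplitude()` fixes it by requiring that the connection-weighted
stimulus activity arriving at the STN be a set fraction (default 6%, at
the 150 Hz reference frequency) of all connection-weighted STN afferents,
closing the self-consistency loop by fixed-point iteration on short
stimulated runs.  The calibrated value ($\approx 9.6\,\mathrm{s^{-1}}$
under the defaults) is recorded in the protocol's metadata.

## Numerics

* **Integrator.** Classical fixed-step RK4 on the 18-variable system, with
  delay history ring buffers; default $dt = 10^{-4}$ s puts the two delays
  at exactly 450 and 350 steps.  Delayed values at half-step stage times
  are linearly interpolated between buffer samples (an $O(dt^2)$ error
  below the RK4 local error for these smooth fields); arbitrary fractional
  delays are supported the same way, with a warning.
* **Drive convention.**  The stimulus and the noise increment are
  sample-and-hold at the step resolution, so the realized drive is exactly
  the zero-order hold of its grid samples; `evoked_potential()` uses the
  matching exact state-space discretization, and the two agree to
  $\sim 10^{-9}$ relative, while RK4 refinement tests confirm fourth-order
  convergence on smooth problems and $<10^{-5}$ relative error against a
  100$\times$ refined delayed reference.
* **Equilibrium seeding.**  Runs add a one-off $10^{-6}$ mV offset to the
  cortical potential at $t = 0$ so that a linearly unstable configuration
  leaves equilibrium at a reproducible time rather than on accumulated
  round-off; at the stable operating state the offset simply decays.  Set
  `seed_offset = 0` for equilibrium-preservation checks (drift stays below
  $10^{-9}$ mV over seconds).
* **Spectra.**  `power_spectrum()` is a Welch estimate: mean removal, Hann
  taper, 4 s segments with 50% overlap by default (0.25 Hz resolution);
  entrainment scans use one segment spanning the whole window for 0.1 Hz
  bins.  The density normalization makes broadband (noise) input satisfy
  Parseval within estimator variance; an isolated sinusoidal line
  integrates to 1.5$\times$ its variance under the Hann taper, a standard
  windowing factor that cancels in every peak-frequency readout and power
  ratio the package reports.  When beta-band peak power is measured under
  stimulation, bins within $\pm 0.5$ Hz of stimulus harmonics inside the
  band are masked so the stimulus line is not mistaken for intrinsic
  activity.

## Reproducible experiments

`run_preset()` packages the figure-level pipelines
(`beta-generation-a/b`, `dbs-onset-150Hz`, `suppression-sweep`,
`gain-vs-fstim`, `direct-vs-indirect`, `fstim-spectrogram`,
`entrainment-scan`).  Every preset resolves its full configuration
(defaults plus overrides, unknown keys rejected), hashes it, and writes
tables, the resolved configuration and a log when given an output
directory; `verify_preset()` re-runs a directory from its stored
configuration and fails if any regenerated table differs.  Scaled-down
switches (shorter durations, coarser grids) are plain configuration
overrides, e.g.

```{r}
run_preset("suppression-sweep",
           overrides = list(run = list(duration = 40, window = c(20, 40),
                                       dt = 1e-4, noise_psd = 0.1,
                                       seed_offset = 1e-6)))
```

The test suite and the acceptance script use 20 s runs analysed on their
final 10 s for sweep points and a single 40 s run (10-30 s window) for the
unstimulated spectrum — sizes at which every reported frequency is stable
to within one bin across seeds.

## Known limitations

* Only the spatially uniform mode is solved; no wavenumber structure, no
  traveling cortical waves.
* Dopamine is implicit in the parameter values; there is no explicit
  nigral population or dopamine dynamics.
* Antidromic cortical activation and pallido-thalamic fiber activation by
  the electrode are not modeled; DBS acts only through the three rate
  channels described above.
* The white-noise excitation stands in for the aggregate stochastic
  background a real network receives; it is spectrally flat and enters
  through a single channel, unlike physiological input, so absolute
  spectral power levels are calibration-dependent even though frequencies
  and power ratios are not.
* Threshold and locking readouts are sensitive to the distance from the
  Hopf point, which lies within a fraction of a percent of the nominal
  couplings (see the operating-regime section).
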