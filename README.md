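# ctbgsim

Neural field simulation of the corticothalamic–basal ganglia (CTBG)
system with population-level deep brain stimulation (DBS) of the
subthalamic nucleus (STN).

Parkinsonian electrophysiology is dominated by two abnormal rhythms —
13–30 Hz (beta) activity in the STN and pallidum and ~4–8 Hz tremor-band
activity — and high-frequency (>100 Hz) electrical stimulation of the STN
suppresses the beta rhythm along with motor symptoms. `ctbgsim` is a tool
for exploring the circuit mechanics behind both observations at the
population level: it simulates nine interacting neural populations
(cortical excitatory/inhibitory, thalamic relay and reticular, striatal
D1/D2, both pallidal segments, and the STN) as a delay differential
system, finds its fixed points, linearizes it into loop gains, drives it
with clinically shaped DBS pulse trains, and quantifies the resulting
spectra.

The model follows the standard neural-field formulation.  Each population
`a` converts mean soma potential to mean firing rate through a sigmoid

    Q_a = Q_a^max / (1 + exp(-(V_a - theta_a) / sigma'))

its soma potential obeys the second-order synaptodendritic response

    (1/(alpha beta)) V_a'' + (1/alpha + 1/beta) V_a' + V_a
        = sum_b nu_ab phi_b(t - tau_ab)

and cortical pyramidal activity propagates as a damped wave, which in the
spatially uniform mode is

    (1/gamma_e^2) phi_e'' + (2/gamma_e) phi_e' + phi_e = Q_e ,

while all short-axon populations satisfy `phi_a = Q_a`.  DBS enters as an
external pulse-rate channel (top-hat pulses, amplitude `phi_x^max`, width
0.7 ms) coupled negatively to the STN and positively to both pallidal
segments.  The packaged parameter set is a nominal parkinsonian state
with a pathologically strong STN→GPe coupling; its operating point is a
lightly damped 26 Hz focus whose resonances are excited by a seeded
stochastic component on the external drive.  See the vignette
(`vignettes/ctbg-dbs-model.Rmd`) for the full account, including why
threshold-type readouts depend on the distance to the nearby Hopf point.

## Worked example

```r
library(ctbgsim)

model <- ctbg_model()          # nominal parkinsonian parameters
states <- solve_steady_states(model)
op <- select_operating_state(states)
op
#> CTBG steady state
#>  population     V0_mV   phi0_s1
#>           e  2.193891  8.154865
#>           i  2.193891  8.154865
#>           r  1.237337  8.259959
#>           s -1.025466  4.218501
#>          d1  5.015482  0.925258
#>          d2  1.231400  0.296825
#>          p1  6.524857 64.658835
#>          p2  5.118028 70.712459
#>           z -3.541168  8.124158
#>   residual: 2.84e-14 s^-1 (4.93e-15 mV potential-equivalent)

cond <- study_conditions(seed = 1)
sim <- simulate_ctbg(model, duration = 40, init = op, noise = cond$noise)
sp <- power_spectrum(sim, "z", t_start = 10, t_end = 30)
sp
#> CTBG spectrum of 'z': 20001 bins to 5000 Hz (resolution 0.25 Hz, 9 segments)
#>   dominant non-DC peak below 60 Hz: 26 Hz (power 1.774)
dominant_peak(sp, 1, 10)$frequency
#> [1] 6.25
```

The STN rate spectrum shows the parkinsonian signature: a dominant 26 Hz
beta peak (with a second harmonic near 52 Hz) and a weaker 6.25 Hz
tremor-band peak.  The linearized loop gains quantify the responsible
circuits — the STN–GPe loop and the hyperdirect pathway are both
pathologically strong:

```r
g <- gains(op, model)
loop_gain(g, ctbg_loops()$stn_gpe)      #> -19.038
loop_gain(g, ctbg_loops()$hyperdirect)  #> -30.485
```

DBS experiments use a pulse train whose amplitude is calibrated so the
stimulus is 6% of the connection-weighted input to the STN:

```r
pr <- calibrate_amplitude(model, stim_protocol(f_stim = 150),
                          target_share = 0.06, init = op)
pr
#> DBS protocol: 150 Hz, width 0.7 ms, amplitude 9.578971 s^-1, onset 0 s
#>   couplings (mV s): zx = -1.2, p1x = 1.2, p2x = 1.2

tab <- suppression_curve(model, pr, seq(100, 200, 10),
                         duration = 20, window = c(10, 20),
                         noise = cond$noise, init = op)
```

`suppression_curve()` returns the 20–30 Hz peak power per stimulation
frequency together with the unstimulated baseline (stimulated beta power
falls by three to four orders of magnitude across the 100–200 Hz scan);
`entrainment_scan()` reports 1:1 locking and intermodulation products for
low-frequency stimulation near the beta peak, and `run_preset()` wraps
these pipelines (plus gain-versus-frequency and direct-versus-pulse-train
comparisons) into hashed, regenerable output bundles.  A thin command-line
front end over the same functions ships at `inst/cli/ctbg.R`
(subcommands `steady`, `simulate`, `spectrum`, `sweep`, `preset`,
`verify`).

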