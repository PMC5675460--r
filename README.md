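# thalamosim

A biophysical simulation of the isolated thalamus — the lateral geniculate
nucleus (high-threshold bursting and relay-mode thalamocortical cells plus
local interneurons) and the reticular nucleus — built to study how two
physiological control parameters move the circuit between distinct
oscillatory states:

* the **ACh/NE neuromodulation level**, implemented as the potassium leak
  conductance `g_KL` of each cell class, and
* the **afferent excitation level**, implemented as the maximal conductance
  `g_input` of 100 Hz Poisson synaptic input.

Every neuron is a single-compartment Hodgkin–Huxley model,

    C_m dV/dt = −g_L (V−E_L) − g_KL (V−E_KL) − Σ I_int − 10⁻³ Σ I_syn / A + 10⁻³ I_app / A,

with T-type (low- and high-threshold), L-type, h-, AHP- and CAN-currents,
dynamic calcium Nernst reversal, AMPA/NMDA/GABA_A synapses with
short-term depression `D = 1 − (1 − D_i(1−U)) exp(−(t−t_i)/τ)`, and gap
junctions `I_gap = (V_post − V_pre)/R_g`.  The network (49 HTC, 144 RTC,
64 IN, 100 RE cells on 2-D grids) is integrated with fixed-step RK4 at
0.02 ms in a compiled core.  Analysis tools compute a simulated LFP
(band-passed mean TC voltage), power spectra, spike phases and the
synchronization index κ = |Σ e^{iφ}|/N, burst statistics, a
state classifier, and entrainment/resonance profiles under periodic
pulse stimulation.

The package is aimed at computational neuroscientists studying
thalamocortical rhythms, state transitions, and the state dependence of
brain stimulation.

## Worked example

```r
library(thalamosim)

rec <- run_named_state("alpha", seed = 1)   # awake, eyes closed; 3 s
summary(rec)
#> Thalamic network recording summary
#>   mean firing rates (Hz): HTC 21.7, RTC 28.3, IN 24.9, RE 32.1
#>   dominant sLFP frequency: 10.28 Hz (peak power 22.4 mV^2)
```

The summary prints each population's mean firing rate over the analysis
window (after a 500 ms settling period) and the dominant frequency of the
simulated LFP — here an alpha-band rhythm paced by synchronized
thalamocortical bursting.  `plot(rec)` shows the spike raster and the
sLFP; `compute_slfp()`, `power_spectrum()`, `population_sync()`,
`classify_state()` and friends expose the individual analysis steps.
Ablation experiments modify the graph first:

```r
net <- ablate(build_network(seed = 1), "gap:HTC-HTC")  # cut HTC gap junctions
st  <- params_for_named_state("delta")
rec <- simulate_thalamus(net, st$g_KL, st$g_input, seed = 1)
```

Stimulation sweeps and the neuromodulation/input transition map are
available as `run_sweep()` / `cmd_sweep()` and `cmd_map()`; a thin command
line wrapper lives in `inst/cli/thalamosim`
(`thalamosim simulate --state delta --seed 1`).

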