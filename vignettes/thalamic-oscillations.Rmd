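---
title: "A conductance-based thalamic network and its oscillatory states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based thalamic network and its oscillatory states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`thalamosim` simulates an isolated thalamic circuit: the lateral geniculate
nucleus (LGN), with high-threshold bursting thalamocortical cells (HTC,
7 x 7 = 49), relay-mode thalamocortical cells (RTC, 12 x 12 = 144) and local
interneurons (IN, 8 x 8 = 64), plus the reticular nucleus (RE,
10 x 10 = 100).  Every neuron is a single Hodgkin-Huxley compartment
(`C_m` = 1 uF/cm^2) obeying

```
C_m dV/dt = -g_L (V - E_L) - g_KL (V - E_KL) - sum(I_int)
            - 1e-3 sum(I_syn)/A + 1e-3 I_app/A
```

with intrinsic currents in uA/cm^2 and synaptic/applied currents in nA
(`A` is the membrane area; the `1e-3/A` factor converts nA to uA/cm^2).
The intrinsic currents are the transient sodium and delayed-rectifier
potassium spike currents, low- and high-threshold T-type calcium currents
(the high-threshold variant is the low-threshold one with both gates
shifted +28 mV), an L-type calcium current, the hyperpolarization-activated
cation current, a calcium-dependent potassium current, and a
calcium-activated nonselective cation current with Michaelis-Menten calcium
sensitivity (half-saturation 0.2 uM).  TC cells carry eight of these, INs
six (no T-type or L-type), REs five (their own T-current kinetics, no
h-current).  Calcium enters a 0.5 um shell, decays with 10 ms (TC/IN) or
100 ms (RE), and sets the calcium reversal potential through the Nernst
equation with the natural logarithm (about +141 mV at the 0.05 uM resting
concentration).

Two parameters move the network between states, following the study design
this package implements:

* the ACh/NE neuromodulation level, expressed as the potassium leak
  conductance `g_KL` per cell type (falling with arousal in TC and RE
  cells, rising in INs), and
* the afferent drive, a 100 Hz Poisson conductance input per neuron with
  per-type increment `g_input` (nS, 5 ms decay, AMPA-like reversal at 0 mV).

The named conditions are deep sleep (delta), light sleep (spindle; a
100 ms x 100 pA pulse into all RE cells at t = 1 s triggers the
oscillation), awake with eyes closed (alpha) and attentive wakefulness
(gamma).  A transition map interpolates `g_KL` linearly between the 0% and
100% endpoints and sweeps the TC-only input conductance from 0 to 20 nS.

Chemical synapses use first-order transmitter binding (0.5 mM, 0.3 ms
pulses, 2 ms axonal delay) for AMPA, NMDA (with the magnesium block
`1/(1+exp(-(V+25)/12.5))`) and GABA_A receptors, all scaled by a
short-term-depression variable (`U` = 0.07, recovery 700 ms).  Gap
junctions couple neighbouring HTC cells (100 MOhm), HTC cells with a 20%
subset of RTC cells, and a 20% subset of RE cells (300 MOhm), with
endpoints at most two lattice units apart.

## Kinetics provenance and calibration

The gating kinetics were transcribed from the standard source models of
this literature: Traub-type sodium/potassium spike currents, the classic
relay-neuron T-type and h-current descriptions, reticular T-current
kinetics, and a high-voltage-activated L-type current.  The exact
functional forms live in `R/kinetics.R`.  Two deliberate departures from
the verbatim sources were required to obtain usable network dynamics and
are the package's own calibration choices:

* the delayed-rectifier activation is shifted so that it supplies graded
  potassium current above about -50 mV; without this the sodium window
  current latches cells at a depolarized plateau near -43 mV;
* the calcium-dependent potassium (AHP) gate uses `alpha = 0.02 [Ca]` (uM)
  and `beta = 0.1` per ms - a brief, strong spike-spacing brake matched to
  the large calcium transients of a 0.5 um shell.  A slower AHP traps every
  state in a hyperpolarized low-threshold bursting cycle.

Maximal conductance densities (see `R/cells.R`) were calibrated against the
qualitative single-cell firing modes the model family is built on:
spontaneous rhythmic low-threshold events near the delta band at the
deep-sleep potassium leak, rebound bursts after release from
hyperpolarization at the light-sleep leak, and depolarized firing under
strong drive.  With one density set serving all four states, the
calibration is a compromise: the delta network oscillates near 4.5 Hz
(reference 3.7) and the alpha state near 10.3 Hz (reference 9.2), but the
light-sleep condition oscillates near 13-16 Hz instead of the 7.9 Hz
spindle band, and the gamma state reaches only ~18 Hz (reference 30.5)
because the TC cells cluster-burst rather than fire tonically at ~31 Hz
under strong drive.  The spindle condition also retains spontaneous TC
bursting, so the trigger dependence of spindles is partial.  These gaps are inherent to the
transcribed kinetics at this calibration and are reported honestly by the
test suite rather than masked.

## Numerical scheme

The engine integrates all membrane, gating and calcium equations with a
fixed-step fourth-order Runge-Kutta method at `dt` = 0.02 ms (halving the
step leaves single-cell spike times stable to a fraction of a
millisecond; the suite checks fourth-order convergence on spike-free
dynamics).  Voltage-dependent gating rates are linearly interpolated from
tables on a 0.05 mV grid built directly from the R kinetics functions, so
the R definitions are the single source of truth.  Gap junctions are
evaluated per Runge-Kutta stage from stage voltages.  Event handling is
aligned to step boundaries: spikes are detected as upward 0 mV crossings
(1.5 ms refractory; the crossing time is interpolated linearly inside the
step), transmitter pulses start one axonal delay later, and the
transmitter-binding equation is advanced with the fourth-order update of
its linear form with the transmitter held constant over a step.  The
synaptic conductances reaching each cell are aggregated per receptor class
and updated in an event-driven fashion; the depression factor of a
connection is held at its post-spike value between presynaptic spikes and
recovered exactly at the next spike (the approximation error is well below
1% because the open-channel fraction decays within tens of milliseconds
while depression recovers over 700 ms).  Gating variables are clamped to
[0, 1] after every step; shell calcium is floored at a nanomolar value.
Cells start at their two-leak fixed point with gates at steady state, and
the first 500 ms of every network run are discarded from analysis.

All randomness - topology draws, leak heterogeneity, Poisson event trains -
derives from R's RNG under a single user-supplied seed, so a run is exactly
reproducible from `(seed, configuration)`.

## Analysis conventions

The simulated LFP is the cell-count-weighted mean TC membrane potential,
mean-subtracted and band-pass filtered 0.5-80 Hz with a linear-phase FIR
filter (order 300 at the 1 kHz analysis rate) applied forward-backward.
A transition band of a fraction of a hertz at the low edge is not
realisable on 2.5 s analysis windows (the filter would outlast the
signal), so the order-300 design is used and the dominant frequency is
taken as the argmax of the zero-padded FFT power spectrum restricted to
0.5-80 Hz.  Power is scaled so a sinusoid of amplitude `a` mV peaks at
`a^2/2`; the classifier's thresholds (1.0 for "oscillatory", 3.0 for
spindle detection) are expressed in these units and are exposed as
arguments.  Spike phases are interpolated linearly between successive
peaks of the sign-reversed sLFP (peaks = local maxima above the 60th
percentile, separated by at least half the dominant period), and the
synchronization index is the modulus of the population's resultant phase
vector.  Bursts are maximal spike groups with intra-burst intervals of at
most 10 ms and at least two spikes.  PETH cross-correlations use 2 ms
bins, mean removal and Pearson normalisation, with the peak searched over
lags up to 250 ms.  Locking ratios in stimulation sweeps are declared when
`|m f_dom - k f_stim| <= 0.5 Hz` for `k, m` up to 3, half the 1 Hz
stimulation grid.

## Problem sizes

Full study runs simulate the complete 357-cell network for 3 s (the
stimulation-sweep mode dwells 1 s per frequency and can cover 1-50 Hz in
one continuous 50 s run).  The test suite uses the same network at 3 s
with two seeds per frequency criterion, miniature 73-cell networks for
engine-level properties, and synthetic signals for the analysis
contracts; the acceptance script averages five seeds per target.  The
451-point transition map is provided as a long-running mode
(`cmd_map()`), spot-checked on a 3 x 5 sub-grid.

## What the generator does and does not emulate

The Poisson drive models asynchronous retinal/cortical input as shot-noise
conductance; it contains no rhythmic structure, no correlations across
cells, and no synaptic depression.  Leak heterogeneity (+/-25% uniform)
and random connectivity are the only other noise sources.  Passing tests
therefore demonstrate the internal consistency of the model and its
analysis chain under these idealisations - not that the biological
thalamus behaves this way, nor that the printed reference values would be
reproduced by a different kinetics transcription.
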