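---
title: "A reduced laminar column model of somatosensory evoked current dipoles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced laminar column model of somatosensory evoked current dipoles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

somasim simulates the primary current-dipole source of somatosensory
evoked M/EEG responses from a conductance-based model of a laminar
neocortical column. The column contains a 10 x 10 grid of layer-2/3 and
layer-5 pyramidal cell pairs plus 35 inhibitory basket cells per layer
(270 cells in total). Pyramidal cells are reduced to three compartments -
a soma carrying fast Na/K spiking conductances and passive proximal and
distal apical compartments coupled by axial conductances - and basket
cells to a single fast-spiking compartment. The L5 distal compartment
additionally carries a small slow depolarizing (calcium-like)
conductance. Compartment update uses exponential Euler at a fixed step
(default `dt = 0.025` ms) with a divergence guard at |V| = 150 mV.

Synapses are dual-exponential conductances (AMPA, NMDA, GABA_A, GABA_B),
peak-normalized so that a unit event produces a conductance equal to its
weight. NMDA receptors on pyramidal compartments carry the standard
Jahr-Stevens magnesium block; basket-cell NMDA is treated as unblocked
(GluN2C/D-like), so the slow excitatory component can contribute at
hyperpolarized potentials. The GABA_A decay constant on basket cells is
25 ms - the value that sets the period of interneuron-generated gamma
(ING) - while GABA_A on pyramidal somata decays in 5 ms. GABA_B is slow
somatic inhibition (rise 2 ms, decay 45 ms). We deviate here from a
shorter 20 ms convention because inhibition with a 20 ms decay cannot
outlast a single gamma cycle: the cumulative hyperpolarization that a
repetitive 40 Hz drive is supposed to build across a burst simply never
accumulates. 45 ms is at the fast end of published GABA_B IPSC decay
constants.

Local connections follow a fixed weight table (in microsiemens):
pyramidal populations excite via AMPA/NMDA, basket populations inhibit
via GABA_A/GABA_B, and every realized synapse is scaled by
`exp(-d / space_constant)` in the grid plane. The network-wide fall-off
constant defaults to 3 grid units; it is not derived from data and only
needs to make nearby cells dominant. Two connection classes carry their
own, tighter spatial spread:

* basket-to-basket inhibition (constant 1.2): with the network-wide
  spread, the summed standing inhibition after one synchronous basket
  volley is so large that the population stays silent for about two
  gamma cycles. The tight spread tunes post-volley recovery to the 25 ms
  GABA_A decay, so drives arriving at the gamma period re-recruit the
  population while faster spacings fall inside the suppressed window.

Proximal (feedforward) drives contact the somatic/basal input zone of
both pyramidal populations and the somata of both basket populations;
distal (feedback) drives contact the distal apical compartments and the
L2/3 basket somata only. Targeting the reduced pyramid's soma rather
than the middle compartment is deliberate: with a middle-compartment
target the upward and downward axial currents nearly cancel, whereas
somatic/basal excitation unambiguously pushes current up the apical
dendrite, which is the defining signature of the proximal pathway
(conversely, distal excitation pushes current down).

The dipole is the sum over pyramidal cells of intracellular axial
current times inter-compartment length, positive upward. L5 apical
lengths are twice the L2/3 lengths, so the aggregate is dominated by L5.
Each trial is baseline-corrected to its resting (pre-drive) level,
multiplied by the experiment's scaling factor (10, 40, and 2500 for the
TE, MN, and LE families), and smoothed with a unit-gain Hamming window
(5 ms during fitting and spectral analysis, 20 ms for final waveforms;
reflection padding preserves the baseline at the edges). Raw model units
are arbitrary; the scaling factor makes amplitudes comparable to nAm
source waveforms in order of magnitude only, and no acceptance quantity
depends on absolute amplitude.

## Drives and experiments

A drive is one exogenous excitatory input: per trial, a single
presynaptic spike time is drawn from a Gaussian and applied
synchronously to every targeted cell with per-target AMPA/NMDA weights.
Trial-to-trial variability comes exclusively from this jitter. Bursts
expand into arithmetic sequences of drives
(`start + k * inter_drive_interval`); aperiodic controls draw times
uniformly over a window, either synchronously or independently per cell.
Negative samples clamp to zero with a warning; samples beyond the trial
window are dropped (that input never arrives within the trial).

The canned experiments reproduce the published drive sequences: the
tactile response (proximal 19.6 +/- 2.5, distal 65.7 +/- 3.8, proximal
90.5 +/- 10.4 ms), the median-nerve sequences before and after
optimization (post-OPS: 20.8 +/- 4.1, 31.6 +/- 2.7, 84.0 +/- 4.5,
134.4 +/- 4.4 ms, with the ~30 ms input distal), and the laser-evoked
family built around a four-input 40 Hz distal burst (post-OPS means
118.8, 145.0, 168.9, 194.5 ms plus a late proximal drive at
256.8 +/- 12.2 ms), together with single-drive, proximal, aperiodic,
asynchronous, and variable-interval controls. Timing parameters are
treated as canonical; per-target conductances are not printed in
machine-readable form anywhere, so the packaged values are hand-tuned
defaults chosen once to reproduce the qualitative deflection sequence of
each response family (signs, ordering, approximate latencies) and are
fully exposed in the configuration objects. Within the LE burst each of
the four drives carries its own conductances, ramping from 0.55x to
about 1.2x of the base set so that cumulative inhibition peaks near the
empirical N1 latency rather than at burst onset; the optimization stage
of the original study likewise fitted each burst drive separately.

A simulation runs `n_trials` independent trials (default 100; the LE
post-OPS configuration with an added early proximal drive defaults to
50, the count used for five-or-more-drive simulations). The trial mean
is the pointwise mean of per-trial traces, smoothed per trial before
averaging. Before the first trial the network is settled for 100 ms
without drives and every trial starts from that resting state.

## Fitting, sensitivity, spectra

Waveforms are scored by RMSE on the overlapping time grid. The
optimizer is a derivative-free staged coordinate search: drives are
visited in order of mean time, and each free parameter receives three
refinement iterations, each evaluating three candidates across a bracket
that then shrinks around the best. Candidates are evaluated at a reduced
trial count (default 25) with 5 ms smoothing to avoid fitting
high-frequency structure; the best configuration is never worse than the
starting one. This matches the stated three-iterations-per-parameter
budget without claiming to reproduce any particular optimizer.

Sensitivity analysis is one-at-a-time: 50 simulations per sweep in which
only the parameter of interest varies - conductances log10-uniform over
1e-5 to 1e-2 uS, timings uniform over the mean +/- 4 ms (MN) or
+/- 10 ms (LE) - under common random numbers, so the reported
per-time-point SD reflects parameter variation rather than jitter.
Named sets `mn_sensitivity` and `le_sensitivity` carry the published
parameter subsets, including the burst inter-drive interval for the LE
case.

Time-frequency maps use Morlet wavelets with m = f/3 cycles, which
fixes sigma = 1/(6 pi) s (about 53 ms) at every frequency, amplitude
normalization A = (1/2 sum |w|^2)^(-1/2), zero padding at least one
wavelet half-length, and alignment to the wavelet center. Trial
averaging happens in the power domain, so non-phase-locked activity
survives. Traces are decimated to 0.5 ms before decomposition - the
3-100 Hz analysis band sits far below that grid's Nyquist limit - and
band peaks break ties toward the lowest frequency.

## Surrogate data

The surrogate generator emulates the canonical deflection structure of
each response family as sums of Gaussian bumps plus white noise: for MN,
a small upward deflection near 20 ms, the dominant downward deflection
at 35-40 ms, a sustained sub-baseline stretch over 50-100 ms, and a
partial rebound; for LE, one large prolonged downward deflection within
100-200 ms and a smaller upward rebound before 300 ms. These are
synthetic stand-ins with free amplitude scale, not recordings: passing
fitting and optimization tests against them demonstrates that the
machinery works on waveforms with the right morphology, not that the
model fits any particular participant's data.

## Scale, determinism, and reproducibility

All randomness flows from integer seeds: trial k of an experiment uses
`base_seed + k`, and each drive separates its stream with a seed offset,
so ensembles are bitwise reproducible. Packaged analyses run at desk
scale: acceptance checks use 25-trial MN ensembles and 25-50-trial LE
ensembles (the original study used 100, or 50 for five-or-more-drive
simulations), and the test suite exercises the integrator mostly on
16-pyramid columns, which preserve every mechanism at a fraction of the
cost. The full 270-cell column integrates a 170 ms trial in roughly one
second.

## Known limitations

* The reduced network does not reproduce the clean 40 Hz / 80 Hz
  trial-mean spectral ridges of the full multi-compartment model. With
  the published per-drive jitter (SD about 10 ms), drive-locked
  periodicity is incoherent across trials, and a homogeneous
  single-compartment basket population with the fixed mutual-inhibition
  weight cannot sustain a free-running 25 ms ING clock: after a full
  synchronous volley the population recovers either much faster or much
  slower than one gamma period. The low-gamma band instead shows a broad
  maximum near 30-36 Hz and the high-gamma band is monotone. The gamma
  resonance is still demonstrable under an exactly periodic 40 Hz burst,
  where basket interspike intervals and the population autocorrelation
  concentrate at ~25-26 ms.
* For the same reason, the periodic-versus-aperiodic burst contrast is
  muted: periodic spacing recruits about 15% more basket spikes and a
  deeper time-averaged dipole, but the minimum of the trial mean - an
  extreme-value statistic on a flat-bottomed trough - is statistically
  indistinguishable between the two at desk-scale trial counts.
* The deepest point of the simulated LE trough follows the third burst
  input, so the trial-mean N1 minimum sits near 174 ms at 50 trials -
  close to, but systematically a few milliseconds later than, the
  ~170 ms empirical anchor. At 25 trials its position scatters by about
  +/- 12 ms across seeds because the trough bottom is broad.
* Absolute dipole amplitudes are not calibrated: only deflection signs,
  ordering, and latencies are meaningful.
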