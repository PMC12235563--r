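# somasim

Simulation of the primary current-dipole source of human somatosensory
evoked responses from a reduced laminar neocortical column.

Evoked responses measured with MEG/EEG and source-localized to primary
somatosensory cortex (SI) have stereotyped shapes: electrical
median-nerve (MN) stimulation produces an upward deflection near 20 ms
(N1), a dominant downward deflection at 35-40 ms (P1), a prolonged
depression, and a rebound; cutaneous laser stimulation (LE) produces a
single large downward deflection near 170 ms followed by a rebound,
accompanied by ~40 and ~80 Hz gamma activity. somasim is for
computational neuroscientists who want to explore, at desk scale, the
laminar circuit mechanisms behind these waveforms: which sequences of
feedforward ("proximal") and feedback ("distal") synaptic drives to a
canonical cortical column reproduce each deflection, and how sensitive
the waveform is to each drive parameter.

## The model

A 10 x 10 grid of L2/3 and L5 pyramidal cell pairs plus 35 basket cells
per layer, connected with fixed weights and exponential spatial
fall-off exp(-d/λ). Pyramidal cells are three-compartment
conductance-based neurons (Hodgkin-Huxley-style Na/K soma, passive
apical compartments); basket cells are single-compartment fast-spiking
cells whose mutual GABA_A inhibition decays in τ ≈ 25 ms, the period of
interneuron gamma (ING). Exogenous drives deliver synchronous
AMPA/NMDA input, with one Gaussian-jittered spike time per drive per
trial: t_k ~ N(μ_k, σ_k). The dipole is

    D(t) = Σ_cells Σ_segments  I_axial(t) · L_segment,

positive for current flowing up the apical dendrites, scaled to nAm and
smoothed with a unit-gain Hamming window. Fitting minimizes the RMSE
between simulated trial-mean and target waveforms via staged coordinate
search over drive times and conductances; sensitivity analysis sweeps
one parameter at a time (50 simulations, conductances log-uniform over
10^-5..10^-2 µS) and stacks the per-time-point SD; spectra use Morlet
wavelets with m = f/3 cycles (σ = 1/(6π) s at every frequency), with
trial averaging in the power domain.

## A worked example

```r
library(somasim)

cfg <- get_experiment("mn_post_ops", n_trials = 25, base_seed = 1)
cfg$smoothing_window <- 5
ens <- run_experiment(cfg)

d <- ens$mean
d$time[which.max(d$aggregate * (d$time <= 30))]   # N1 latency (ms)
#> [1] 20.05
w <- which(d$time >= 20 & d$time <= 60)
d$time[w][which.min(d$aggregate[w])]              # P1 latency (ms)
#> [1] 36.225
```

The trial-mean MN dipole peaks upward at ~20 ms — the feedforward
thalamocortical volley arrives, spikes the pyramidal cells, and their
backpropagating action potentials push current up the apical dendrites
— then plunges to its dominant trough at ~36 ms, driven by the early
distal (feedback) drive at ~31.6 ms pushing current down the apical
dendrites together with recruited somatic inhibition. Removing that
single drive (`get_experiment("mn_no_early_distal")`) shrinks the
trough by more than half: the distinct P1 requires an early feedback
input.

For the laser-evoked response:

```r
le <- get_experiment("le_post_ops", n_trials = 25, base_seed = 1)
le$smoothing_window <- 5
ens <- run_experiment(le)
tfr <- trial_mean_tfr(ens)
ens$mean$time[which.min(ens$mean$aggregate)]      # N1 trough latency (ms)
band_peak(tfr, c(30, 60), c(100, 250))            # low-gamma peak (Hz)
```

Here a burst of four distal drives at ~25 ms intervals recruits
repeated basket-cell volleys whose cumulative somatic inhibition builds
the deep, prolonged N1 trough; a late proximal drive at ~257 ms
produces the rebound.

A command-line interface wraps the same functions
(`exec/somasim simulate|optimize|sensitivity|tfr|synth`); every run
writes a manifest with the resolved configuration, seed, and output
digests.

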