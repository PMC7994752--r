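---
title: "Methods: adaptive-threshold recurrent spiking networks and reward propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-threshold recurrent spiking networks and reward propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnn)
```

## The model

`rsnn` implements a layered recurrent spiking network for sequential
classification. Input spectrograms (frequency bands × time frames) are fed
one frame per integration step; hidden layers consist of two-channel leaky
integrate-and-fire (LIF) neurons with spike-driven adaptive thresholds and
sparse random recurrent loops; a non-spiking leaky-integrator readout
accumulates the last hidden layer's spikes into per-class scores.

### Membrane dynamics

Each hidden neuron carries two membrane channels. Per step of length `dt`
(forward Euler):

* the **feedforward** channel integrates the weighted input
  (`I_ff = W_f' x_t`), leaks toward `V_rest` at rate `g/C`, and is the
  first to be tested against the effective threshold;
* the **recurrent** channel integrates the same layer's previous-step
  spikes through the masked recurrent matrix (`I_rec = W_r' s_{t-1}`) and
  leaks toward 0.

The crossing test uses the *total* potential `V = V_f + V_r` against the
effective threshold `V_th + γ a`. The two channels are evaluated
sequentially within a step (feedforward first, then recurrent), each with
its own spike flag, reset and refractory clock, so a single step can emit
`S = S_f + S_r ∈ {0, 1, 2}` spikes.

Several points in this scheme are deliberate readings of an
under-determined formulation, and are worth stating explicitly:

* **Leak sign.** The leak is implemented as decay toward the resting
  potential, `−g (V − V_rest)/C`. A positive-feedback sign would make rest
  unstable and the neuron non-leaky.
* **Leak gating.** The leak term is gated by `(1 − S)` with `S` the
  previous step's total spike count, clamped below at 0 — `S = 2` must not
  reverse the leak's sign.
* **Recurrent-channel leak.** The recurrent channel leaks toward 0 rather
  than `V_rest`: it carries deviations from rest, and the resting offset
  already lives on the feedforward channel. An unleaked recurrent channel
  would accumulate drive without bound.
* **Threshold crossing.** The neuron fires when `V ≥ V_th + γ a`. An exact
  equality test would be measure-zero in floating point.
* **Refractoriness.** After a spike at `t_s`, the spiking channel is
  clamped at `V_reset` (incoming current discarded, flag not re-raised)
  while `t − t_s ≤ τ_ref`, i.e. through the *full* refractory period; it
  may fire again strictly afterwards. At `dt = 1` ms this makes
  `τ_ref = 1` ms block exactly the next step — a suprathreshold-driven
  neuron can spike at most every second step — whereas a strict `<` would
  never block anything on the integer grid. `τ_ref = 0` disables blocking.
* **Adaptation placement.** The adaptation current can be written either
  as a term `−γ a` in the membrane equation or as a raised threshold
  `V_th + γ a`; the two coincide at the crossing condition. The raised
  threshold is used, avoiding double-counting.

### Adaptive threshold

Each neuron's adaptation variable follows
`da/dt = (α − 1) a + β (S_f + S_r)` with `0 ≤ α < 1`, `β ≥ 0`. Under a
constant spike drive it converges to `a* = β/(1 − α) · S`; with the default
`α = 0.9`, `β = 0.1` that is 0, 1 and 2 for 0, 1 and 2 spikes per step
(`threshold_equilibrium()` gives the closed form, and the package's tests
confirm the simulated fixed point to `1e-6`). Neurons that fire often thus
become harder to fire — spike-frequency adaptation. `γ` couples `a` into
the threshold; `use_adaptive_threshold = FALSE` (equivalently `γ = 0`) is
the plasticity ablation.

A property worth its caveat: with *matched input currents*, raising
thresholds never adds spikes (`γ = 1` spike counts ≤ `γ = 0`, verified
across random matched-current simulations). In a *recurrent* network the
two runs feed themselves different spike trains, so the premise fails and
rare rearrangement violations occur; the package's tests therefore assert
monotonicity where inputs are genuinely identical (matched-current layers
and feedforward configurations).

### Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `C` | 1 µF/cm² | membrane capacitance |
| `g` | 0.2 nS | leak conductance |
| `V_rest`, `V_reset` | 0 mV | resting / reset potential |
| `V_th` | 0.5 mV | base firing threshold |
| `τ_ref` | 1 ms | refractory period per channel |
| `dt` | 1 ms | Euler step (one spectrogram frame per step) |
| `α`, `β`, `γ` | 0.9, 0.1, 1 | adaptation decay, drive, coupling |
| `density` | 0.5 | fraction of permitted recurrent connections |
| `V_window` | 0.5 mV | surrogate boxcar half-width |
| batch, optimiser | 50, Adam (0.9/0.999/1e-8) | training loop |

The units follow the source convention for this class of models: nominal
biophysical units with dimensionless weights and currents; no exact unit
calibration is intended.

## Connectivity and initialisation

Feedforward weights are Gaussian with scale `1/sqrt(fan-in)`. Recurrent
connectivity is fixed at construction by a Bernoulli(density) mask over
*all* entries — self-connections included, since uniform random
connectivity implies no structural exclusion — and the mask is re-applied
after every update, so pruned weights are exactly zero forever. The
feedback projections `B` (one per hidden layer, independent even at equal
widths) have entries uniform on `[−1/√K, +1/√K]` for `K` classes — the
usual feedback-alignment scaling; their magnitude only rescales the
effective learning rate. `B` is drawn once and never trained.

## Learning rules

Spikes are non-differentiable, so both rules gate their updates with the
boxcar surrogate `∂S/∂V = 1` iff `|V − V_th_eff| < V_window` (strict
inequality; the boundary maps to 0). The potential used for gating — and
as the layer state `h` below — is the pre-reset total potential at the
step's crossing test, i.e. the quantity actually compared to the
threshold.

**Reward propagation.** The teaching signal is the label itself: the
one-hot vector repeated at every step (`make_reward_signal()`). For each
hidden layer, the per-step error is the projected-target-minus-state
difference `B·RP_t − h_t` (`reward_gradient()`); the weight update chains
it through the surrogate gate and the presynaptic activity:

* `ΔW_f ∝ Σ_t x_t ⊗ [(B·RP_t − h_t) ⊙ sg_t]`
* `ΔW_r ∝ Σ_t s_{t−1} ⊗ [(Grad_{t+1} + B·RP_t − h_t) ⊙ sg_t]`, masked,

where `Grad_{t+1}` is the next step's gated error flowed backward once
through `W_r` (truncation depth 1 by default; `rec_depth` deepens it).
The sign is oriented so a small step descends `‖h − B·RP‖²` — the
orientation under which the rule demonstrably converges. Because each
layer's update uses only its own trace, its own `B` and the global label,
all hidden layers update in parallel; the tests assert bitwise
order-independence. The readout, being a non-spiking integrator outside
the scope of the hidden-layer rule, is trained by the matching delta rule
on the time-averaged output versus the one-hot label.

**Pseudo-BP comparator.** The same machinery driven by the output MSE
error chained layer-by-layer through `W_out` and the `W_f` matrices,
gated by the same surrogate — conventional spatial backpropagation with
one-step recurrent credit, for contrast with the global rule.

**Loss and schedule.** MSE between the time-averaged readout and the
one-hot label; Adam; the learning rate is multiplied by `lr_factor` (0.5)
every `lr_step_every` (100) epochs, a stepwise schedule starting from the
base rate. The package default is the reference base rate `1e-3`; the
synthetic-task experiments below use `5e-3`, the rate at which reward
propagation converges comfortably within a 30-epoch window on these small
tasks.

## Input coding

Two-part coding: (i) the raw spectrogram is rescaled by one scalar —
`fit_input_scale()` maps the dataset's 99th-percentile energy to 1, so
rare extreme bins do not set the scale — and fed frame-by-frame as analog
currents into the first layer; (ii) inside the network, signals become
binary spikes at the neurons' thresholds. A config switch
(`input_encoding = "binary"`) instead thresholds the input itself at
`V_th` (strictly above → 1), for experiments that want a fully binary
interface.

## The synthetic task

The generator (`synth_spec()`, `generate_dataset()`) emulates the
statistical structure of filterbank speech features at the reference
geometry (39 bands × 39 frames by default): one fixed smooth band×frame
template per class — a band-limited random field, built by bilinear
interpolation of coarse Gaussian noise, thresholded to the requested
sparsity (default 25% active cells) and normalised to unit peak — plus
i.i.d. Gaussian noise per sample, clipped at zero. Smooth templates spread
class evidence over frames, which is what gives the recurrent channel
something to integrate. `noise_sd = 0.1` against unit-peak templates is
the "easy" regime: the nearest-template classifier (the analytic reference
included as `nearest_template()`) is exact there, and its accuracy decays
monotonically as `noise_sd` grows.

What the generator does *not* emulate: variable-length utterances,
within-class temporal warping, correlated (pink/babble) noise, and
phoneme-level structure. Tests passing on this task therefore demonstrate
the mechanics and relative behaviour of the rules, not speech-recognition
performance.

**Corruption operator.** `add_uniform_noise()` replaces a fixed fraction
of entries (`round(proportion · n)`, chosen without replacement) with
uniform draws over the data's value range. The robustness protocol
(`run_robustness_experiment()`) trains under *noise-noise* (train and test
corrupted) and *noiseless-noise* (test only) regimes and reports
`RobustRatio = Acc_noiseless,noise / Acc_noise,noise`. At proportion 0 the
two regimes coincide and the ratio is exactly 1; the ratio is reported as
undefined where the denominator is 0, and values above 1 are possible
(training noise can hurt). The dense comparator is a matched-width
single-hidden-layer tanh network on the flattened input, trained with the
same optimiser and loss — deliberately the smallest reasonable non-spiking
baseline, not a tuned competitor.

At 50% corruption the spiking network's ratio stays near 1 while the dense
baseline's drops well below — but at these desk-scale sizes the spiking
model's *absolute* accuracy under 50% corruption is low in both regimes;
the supported claim is the ordering of the ratios, which the test suite
asserts as a median over seeds.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: learnability uses the
4-class easy task (100 training samples, 200 hidden neurons, 30 epochs);
the robustness contrast uses 100 hidden neurons, 30 epochs and 5 seeds at
proportion 0.5; invariant sweeps use layers of 50–100 neurons over
10^3–10^4 random-input steps. All randomness flows from explicit integer
seeds; rebuilding a model or regenerating a dataset with the same seed is
bitwise reproducible, and `train_network()` re-seeds from its config so
repeated fits are identical. Ties in the argmax readout resolve to the
lowest class index. Degenerate inputs are rejected loudly: non-finite
currents, states or gradients raise errors rather than propagate.

## Known limitations

* Single-step truncation of recurrent credit is the default; full
  backpropagation-through-time is out of scope.
* The readout delta rule is heuristic (the leaky integrator's gradient is
  approximated by the accumulated spike counts); it is simple and
  sufficient for the tasks here.
* The layer abstraction supports stacks of recurrent hidden layers, but
  the shipped experiments use one hidden layer; convolutional front-ends
  are not provided.
* Audio preprocessing (FFT/MFCC) is upstream of the package: samples enter
  as precomputed spectrograms via the delimited-text loader or the
  generator.
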