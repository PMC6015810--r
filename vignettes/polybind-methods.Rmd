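---
title: "Methods: spiking dynamics, plasticity, and the binding analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiking dynamics, plasticity, and the binding analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`polybind` simulates hierarchical spiking networks in which *polychronous*
activity — reproducible, time-staggered spike patterns enabled by
heterogeneous axonal conduction delays — emerges through learning, and in
which three-neuron *binding circuits* develop: a binder neuron that fires
if and only if a low-level feature neuron causally drove a high-level
feature neuron.

## Membrane and synapse dynamics

Every neuron is a conductance-based leaky integrate-and-fire unit,

$$\tau_m \frac{dV_i}{dt} = (V_0 - V_i) + R\, I_i(t), \qquad
  I_i(t) = \sum_j g_{ij}(t)\,\bigl(\hat V_{c(j)} - V_i(t)\bigr),$$

with $\tau_m = C_m / g_0$ and $R = 1/g_0$. Units are mV, ms, nS, pF and pA
throughout; pF/nS = ms keeps the equation dimensionally closed. The
excitatory cell uses $C_m = 500$ pF, $g_0 = 25$ nS (so $\tau_m = 20$ ms),
rest $-74$ mV, threshold $-53$ mV, reset $-57$ mV; the inhibitory cell
$C_m = 214$ pF, $g_0 = 18$ nS, rest $-82$ mV, reset $-58$ mV. We derive
$\tau_m$ from $C_m/g_0$ everywhere; for the inhibitory cell this gives
11.89 ms, within 1% of the conventionally quoted 12 ms — the derived value
is used. The absolute refractory period is 2 ms: after a spike the
membrane is clamped at the reset potential while synaptic conductances
continue to decay and accumulate (common LIF practice).

Each synapse carries a conductance $g_{ij}$ that decays exponentially with
a class-specific time constant $\tau_g$ and jumps by $\lambda \,\Delta
g_{ij}$ when a presynaptic spike *arrives*, i.e. at emission time plus the
synapse's axonal delay $\Delta t_{ij}$. The efficacy $\Delta g_{ij} \in
[0,1]$ is the plastic weight; $\lambda$ is a per-class scaling bound
(0.4 nS for retina-to-layer-1, 1.6 nS for excitatory-excitatory, 40 nS
and 80 nS for the fixed excitatory-inhibitory loop). Excitatory reversal
is 0 mV, inhibitory $-70$ mV; excitatory-excitatory conductances decay
with $\tau_g = 150$ ms, the interneuron loop with 2 ms and 5 ms.

### Numerical scheme

Forward Euler with $\Delta t = 0.02$ ms (the reference step; the scaled
experiment drivers use 0.1 ms, which moves first-spike times by well under
0.05 ms — the suite checks this convergence). Within one step the order
is: (1) arrivals due this step are delivered, (2) one Euler step of the
membrane equation, (3) threshold detection, stamping spikes at the end of
the step, (4) delivery scheduling at emission + delay, (5) conductance
decay by the exact factor $e^{-\Delta t/\tau_g}$ (unconditionally stable,
equal to the Euler factor in the limit). Arrivals precede detection so an
arrival can trigger a spike in its own step; delays are rounded to the
nearest step with a floor of one step, so even a zero-delay draw from a
multi-contact delay interval stays causal.

Two implementations exist and are tested against each other: a pure-R
stepper (`integrate_step()`, `update_conductances()`,
`detect_spikes_and_reset()`, `schedule_deliveries()`, composed by
`run_trial_r()`) that keeps per-synapse conductances exactly as the model
states them, and a compiled engine (`run_trial()`) that aggregates
conductances per (neuron, synapse class) — algebraically identical because
decay is linear and $\tau_g$, $\hat V$ are shared within a class — and
decays STDP traces lazily between the events that touch them. The suite
asserts spike-for-spike and weight-for-weight agreement.

## Trace STDP

Plasticity acts on all excitatory-to-excitatory weights. A presynaptic
trace $C_{ij} \in [0,1]$ models transmitter concentration and is driven at
spike *arrival* (not emission, so delay structure matters to learning):
$C \leftarrow C + \alpha_C (1 - C)$, decaying with $\tau_C$. A
postsynaptic trace $D_i$ models NMDA-receptor unblocking and is driven at
postsynaptic spikes with $\alpha_D$, decaying with $\tau_D$. The weight
update is event-driven and multiplicative:

* on a postsynaptic spike, every plastic afferent potentiates:
  $\Delta g \leftarrow \Delta g + \rho\, C_{ij} (1 - \Delta g)$ (LTP);
* on a presynaptic arrival, the synapse depresses first, then $C$ is
  driven: $\Delta g \leftarrow \Delta g - \rho\, D_i\, \Delta g$ (LTD).

The soft multiplicative bounds confine weights to $[0,1]$ without
clipping; the saturating trace drive does the same for $C$ and $D$ when
$0 \le \alpha \le 1$. $\alpha_C = \alpha_D = 0.5$ and $\rho = 0.1$
throughout. The source rule for this form of plasticity names a weight time constant
$\tau_{\Delta g}$ without assigning it a value; we absorb it into the
event-driven learning rate $\rho$, which reproduces the rule's verbal
semantics (high $C$ at a post spike potentiates; high $D$ at a pre arrival
depresses). When a pre arrival and a post spike fall in the same step,
arrivals are processed first (LTD before LTP), mirroring the causal
ordering of the integration loop. The conductance jump of an arriving
spike uses the weight as it stands at arrival, before that same arrival's
LTD.

## Visual front end

Images are encoded by a Gabor filter bank modelling V1 simple cells: four
orientations $\{0, \pi/4, \pi/2, 3\pi/4\}$, two phases $\{0, \pi\}$,
wavelength 2 px, aspect ratio 0.5, spatial bandwidth 1.5 octaves. The
envelope width follows the standard octave-bandwidth relation
$\sigma = (\lambda/\pi)\sqrt{\ln 2/2}\,(2^b+1)/(2^b-1)$. Responses are
half-rectified — the opposite-phase pair supplies the ON/OFF
decomposition — normalized by the maximum response across the whole bank
for that image, and scaled to a 100 Hz ceiling. Input units then emit
homogeneous Poisson trains at these rates; each fresh Poisson seed is one
"transform" of the stimulus, the unit over which the information analyses
average. The training set is three programmatic outline drawings (circle,
heart, star) generated by `make_shape_image()`.

# Architectures

## Two-layer model

1000 Poisson input units, all driven at 50 Hz (the flat stimulus), project
with probability 0.2 and delays uniform on [1, 10] ms to 1000 excitatory
LIF neurons, which project with probability 0.02 and delays uniform on
[1, 30] ms to a second 1000-neuron layer. All connections are plastic;
training uses $\tau_C = 100$ ms, $\tau_D = 150$ ms, $\rho = 0.1$. The
protocol is 10 pre-training test trials (STDP off), 10 training
presentations, 10 post-training test trials re-using the pre-training
Poisson seeds so comparisons are paired. The delay text for the
layer-1-to-layer-2 stage is taken as [1, 30] ms (the running-text value;
a figure caption says [0, 30]); the bound is exposed in the builder. The
synchrony control sets every layer-1-to-layer-2 delay to exactly 1 ms
with otherwise identical wiring and seeds.

**Initial weights.** The model statement is silent on initialization.
With weights uniform on $[0,1]$, the expected conductance inflow per
layer-1 neuron is $N_\mathrm{aff}\, r\, \lambda\, \bar w \approx 200
\times 50\,\mathrm{Hz} \times 1.6\,\mathrm{nS} \times 0.5$, which with
$\tau_g = 150$ ms accumulates past the threshold conductance
$g^\* = g_0 (V_0 - \Theta)/(\Theta - \hat V) \approx 9.9$ nS within about
a millisecond: every neuron would fire at the refractory limit from the
first milliseconds of every trial, and the count of all-trial responders
could never increase with training — contradicting the phenomenon the
experiment demonstrates. We therefore initialize plastic weights uniform
on $[0, 0.05]$, chosen so the expected time to accumulate $g^\*$ is a few
tens of milliseconds: first spikes then fall inside the 200 ms
presentation with realistic latencies, and before training only part of
each layer responds on every trial. The four-layer model keeps $[0,1]$
initialization: its inhibitory loop balances the drive.

## Four-layer model

Four layers, each a 64x64 grid of excitatory and a 32x32 grid of
inhibitory neurons, driven by a 128x128 retina with eight Gabor channels
per location. Topographic fan-in: each postsynaptic neuron samples its
afferents from a Euclidean disc around its proportionally mapped position
on the presynaptic grid — no wraparound (a retina has borders; wraparound
would fabricate long-range binding), sampling without replacement unless
the disc is smaller than the requested count (then with replacement,
logged; this is routine for the radius-1.0 projections). Feedforward
counts/radii per layer are 30/1.0, 100/8, 100/12, 100/16; feedback and
lateral pathways contribute 10 afferents each (radii 8 and 4) when
enabled; the interneuron loop uses 30 afferents each way (radii 1 and 8).
Delays are uniform on [0.1, 10] ms. The conductance scaling entries are
read as bounds on the product $\lambda \Delta g$, i.e. the jump of a
weight-1 synapse.

**Desk scale.** The reference 64x64 grids are expensive; the experiment
drivers default to 16x16 excitatory grids with a 32x32 retina. Only the
grids shrink: per-neuron fan-in counts and radii keep their reference
values, so every neuron's input statistics match the full model and the
dynamical regime is preserved (scaling the counts with grid area would
starve every neuron of drive and silence the network). Multi-contact
variants represent each plastic pre/post pair by $M$ synapses with
independent delays from [0, 10] ms and independent initial weights.

**Presentation duration.** Unstated in the model description. With
$\tau_g = 150$ ms on all excitatory-excitatory synapses, feedforward
conductances reach $1 - e^{-t/\tau_g}$ of steady state; at 200 ms the
third and fourth layers are still silent, while by 500 ms all four layers
engage (both at desk and reference scale). The four-layer drivers
therefore use 500 ms presentations; the two-layer experiment, which has
only two synaptic stages, uses 200 ms. Between presentations the membrane
potentials, conductances and traces are reset; weights persist.

**Training schedule and STDP time constants.** "Repeated presentation in
turn" is unquantified; the drivers default to 10 sweeps over the three
stimuli (30 presentations), exposed in the configuration. The base-run
STDP time constants are likewise unspecified (the parameter table lists
the sweep set {5, 25, 125} ms). The two regimes behave very differently
at desk scale: with $\tau_C = \tau_D = 5$ ms the traces only bridge
coincidences a few ms apart, and within a 30-presentation schedule far
too few such events accumulate to organize selectivity — the network is
simply undertrained, indistinguishable from baseline; with 125 ms the
rule integrates over whole-presentation rate correlations (an
effectively rate-Hebbian regime) and converges within the schedule. The
base four-layer runs therefore default to 125 ms, and the sweep driver
compares all of {5, 25, 125} ms. This has a consequence worth stating
plainly: the full-scale finding that *short* time constants
produce the most maximal-information spike pairs rests on training long
enough for the slow, temporally precise learning to accumulate, and does
not reproduce at desk scale within a desk-scale schedule — at 10 sweeps
the comparison reverses (measured: 0 maximal-information pairs at 5 ms,
2 at 25 ms, 109 at 125 ms on 16x16 grids). The suite asserts the
full-scale direction and reports it as failing rather than weakening the
check.

The multi-contact experiment is different: selective strengthening of
one of a pair's two contacts is a *local* temporal-precision phenomenon
— the presynaptic trace must decay appreciably over the up-to-10 ms
difference between the two contact delays, otherwise both contacts see
identical trace statistics and their weights converge rather than
diverge. The multi-contact driver therefore trains with
$\tau_C = \tau_D = 5$ ms, where the trace decay over a delay
difference is substantial. Even so, majority gap *growth* additionally
requires postsynaptic spikes phase-locked to particular arrival delays
(emerged polychronous structure), and the multiplicative rule compresses
the initially independent contact weights toward a shared equilibrium;
the acceptance script computes the realized fraction of driven pairs
whose gap widens, and the suite asserts the full-scale majority-divergence
direction, reporting it as failing at desk scale rather than weakening
it.

# Analyses

## Single-cell stimulus information

Firing rates per (cell, stimulus, transform) are discretized into
equal-width bins spanning [0, max rate] per cell (default 10 bins;
right-closed bins with zero always in bin 0, so a silent cell is
unambiguous). For each cell and stimulus,

$$I(s, \mathbf R) = \sum_r P(r \mid s) \log_2 \frac{P(r \mid s)}{P(r)},$$

with $P(r)$ the transform-weighted marginal. The ceiling is $\log_2 n$
bits for $n$ stimuli — 1.58 bits for three — attained by a cell responding
in a unique bin to every transform of exactly one stimulus. The binning
choice (equal-width, count configurable) is ours; the source defers the
details to its own reference.

## Spike-pair information

A spike-pair "polychronous group" (i, j, d) occurs in a transform when
neuron i spikes within interval bin $d$ after any spike of neuron j; the
lag window [0, 10] ms is divided into ten 1 ms bins. Occurrence is binary
per transform (spike-count weighting is available behind a flag); the
per-stimulus occurrence probabilities form the response table fed to the
same information formula, so a pair present in every transform of exactly
one of three stimuli carries 1.58 bits. The pair table marginalizes over
absolute spike time within a presentation; only the lag $d$ enters.

## First-spike precision

Per neuron, over the 10 test trials: included only if it spiked in every
trial ("responded" = at least one spike in the presentation window); then
the mean and sample standard deviation ($n-1$) of its first-spike time.
The medians of these standard deviations per layer, before and after
training, quantify the sharpening of temporal structure; the
across-neuron standard deviation of the mean first-spike times measures
how spread out (polychronous) versus clustered (synchronous) the layer's
timing is.

## Binding circuits

`find_binding_circuits()` returns every ordered triple (low 1, high 2,
binder 3) whose synapses 1-&gt;2, 1-&gt;3, 2-&gt;3 all exceed a weight
threshold (default half the maximum weight) and whose delays satisfy
$|\Delta_{(3,1)} - (\Delta_{(2,1)} + \Delta_{(3,2)})| \le$ 1 ms (one lag
bin): the direct spike from 1 and the indirect spike relayed through 2
then reach the binder together. Layers of all members are recorded so the
placement of binders in higher layers can be tabulated. The detector is
validated against exhaustive triple enumeration on random networks.

`verify_binding_behavior()` probes a triple in an isolated runnable
circuit: strong, brief drive synapses (1000 nS, $\tau_g = 0.3$ ms) make
externally driven neurons emit exactly one spike, and the two convergent
binder afferents use 100 nS with $\tau_g = 1$ ms, calibrated so one volley
is subthreshold while two volleys within about 1.5 ms fire the binder.
A 2 ms synaptic constant — the natural first choice for a "fast" probe —
leaves no usable coincidence margin here: with the 20 ms membrane,
temporal summation across volleys dominates and the window degenerates
(razor-thin just above one-volley threshold, many ms wide just below it),
so the probe uses 1 ms. The contract holds iff the binder fires under
causal drive (neuron 1 firing neuron 2 through the circuit) and stays
silent both when neuron 2 fires alone and when neurons 1 and 2 are driven
independently at non-causal offsets.

# What the synthetic stimuli do and do not show

The programmatic circle/heart/star outlines emulate the reference training
set's geometry (closed centred outlines of distinct curvature content) but
are not pixel-faithful reproductions; the flat 50 Hz stimulus is exact by
construction. Poisson inputs carry no temporal structure, so any
spatio-temporal regularity in higher layers is produced by the network —
that is the point of the design — but real retinal input has correlations
these tests do not probe. Desk-scale grids preserve per-neuron input
statistics, not population sizes: absolute counts of maximal-information
cells/pairs are smaller than at reference scale, fragile across wiring
seeds (reaching the exact ceiling over all transforms of one stimulus is
a near-threshold event in a 256-cell output layer), and only directions
(trained vs untrained, short vs long STDP constants, one vs two contacts,
broad vs uniform delays) are meaningful. All stochastic runs derive every
seed from a single master seed through a counter scheme
(`derive_seed()`), so adding trials never perturbs earlier ones and every
figure-level number is bit-reproducible.

# Known limitations

* No adaptive or exponential integrate-and-fire variants, no synaptic
  depression/facilitation, no NMDA voltage dependence ($D$ is a trace,
  not a channel), no off-grid event-driven integration.
* No triplet STDP, heterosynaptic normalization, or reward modulation.
* Binding detection covers three-neuron triplets (with multi-contact
  synapse combinations), not deeper multi-binder chains.
* The information estimators use plug-in probabilities over 10 transforms
  and carry the usual small-sample bias; the permutation control in the
  suite shows shuffled labels sit near zero bits.
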