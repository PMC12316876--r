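---
title: "A spiking attractor model of item-in-context episodic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking attractor model of item-in-context episodic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bcpnnet)
```

`bcpnnet` simulates a pair of reciprocally connected cortical attractor
networks — an Item network and a Context network — performing an
item-in-context recognition task: odors (items) are judged new or old
relative to the currently active context, and only context-appropriate
novelty is rewarded.  Episodic memory (the learned item–context binding)
is deliberately put in conflict with, or in synergy with, short-term
recency effects carried by synaptic augmentation and learned intrinsic
excitability.  This vignette describes the model, the choices made where
the design was genuinely open, and what the scaled-down test
configuration does and does not show.

## Neuron and synapse model

Cells are adaptive exponential integrate-and-fire (AdEx) point neurons,

$$C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_t)/\Delta_T}
  - I_w + I_\beta + I_{syn} + I_{ext},
  \qquad \tau_{I_w} \dot I_w = -I_w,$$

with spike-triggered adaptation only (`I_w += b` on each spike; there is
no subthreshold adaptation term).  `I_beta` is a learned
intrinsic-excitability current (below).  Synapses are conductance based
with exponential decay per receptor (AMPA 5 ms, NMDA 100 ms, GABA 5 ms;
reversals 0, 0, −75 mV).  Glutamatergic connections carry
Tsodyks–Markram short-term state: utilization $u$ relaxes to $U = 0.2$
with the augmentation constant $\tau_A = 5$ s, resources $x$ recover to 1
with $\tau_D = 280$ ms, and a spike applies the facilitation increment
$u \mathrel{+}= U(1-u)$ *before* release, releases $u\,x$, and depletes
$x$ by that fraction.  The ordering at the spike instant is ambiguous in
the differential form (both jump terms are written with the same $u$);
the facilitation-first ("u-plus") convention standard for facilitating
synapses is used, which makes the very first release from rest
$U + U(1-U) = 0.36$ of the peak conductance.

## Bayesian–Hebbian (BCPNN) plasticity

Each plastic connection filters pre- and postsynaptic spiking through a
cascade of exponential traces: fast $Z$ traces (time constants equal to
the AMPA and NMDA decays — two components per connection), eligibility
traces $E$ ($\tau_E = 500$ ms; the co-trace $E_{ij}$ low-passes
$Z_i Z_j$), and probability traces $P$ ($\tau_P = 30$ s) whose update is
scaled by the learning-rate factor $\kappa$.  Weights and biases are

$$w_{ij} = w_{gain} \log\frac{P_{ij}}{P_i P_j}, \qquad
  I_{\beta_j} = \beta_{gain} \log P_j .$$

Negative weights (anti-correlated activity) are delivered as positive
conductance at the GABA reversal — disynaptic inhibition through
double-bouquet cells that are not explicitly simulated.  Reward raises
$\kappa$ from 0.3 to 1 for 250 ms on the associative (between-network)
connections, starting 250 ms after the rewarded choice; the eligibility
traces carry the decision-time co-activity into that window
($e^{-250/500} \approx 0.61$ of its peak survives the delay), which is
what makes delayed reward credit the right synapses.

Numerical treatment: between events the cascade is linear, so the engine
propagates every trace *exactly* (closed-form sums of exponentials) and
touches a connection only when something happens to it — a delayed
presynaptic arrival, a postsynaptic spike, or a global synchronization
when $\kappa$ changes or a snapshot is taken.  A spike is a rectangular
pulse of duration `t_spike` (1 ms) and height $1/(f_{max} t_{spike})$
lumped into an instantaneous $Z$ increment equal to the pulse's terminal
response; the dense-integration reference in the test suite confirms the
event-driven path to well under a percent.  Setting $\kappa = 0$ leaves
the $P$ traces bit-identical by construction (the propagator multiplies
the $P$ stage by $e^{-\kappa \Delta t / \tau_P} = 1$ exactly).  Weights
are recomputed from the probability traces at every delivery, so the
conductance always uses the current weight — fresher than any fixed
refresh cadence, at the same cost.  The $P_{ij}$ stage low-passes the
co-eligibility $E_{ij}$; the printed equation set can also be read as
low-passing the product $E_i E_j$, but that would leave the defined
co-trace unused and was treated as a typographical slip.

Two unstated details were resolved as follows and are configurable: the
spike-pulse duration `t_spike` defaults to 1 ms (the convention of the
published spiking BCPNN lineage), and the intrinsic-excitability bias is
computed from the slow (NMDA-component, rate-like) $P_j$ trace
(`bias_component = "nmda"`), with the fast component available as an
alternative.  The lowest-rate parameter `f_min` (0.2 Hz) is stored for
completeness but enters no update equation.

## Architecture, preloading and delays

Each network is a grid of hypercolumns (HC, 0.5 mm diameter) of 16
minicolumns (MC); at full scale 9 HCs per network with 30 pyramidal and
4 basket cells per MC (8640 excitatory, 1152 inhibitory cells in total).
Pyramidal–pyramidal connectivity is drawn independently per pair:
recurrent within an MC and long-range within a network at probability
0.2, associative between the networks at 0.04; pyramidal/basket loops at
0.7 stay inside their HC (3 nS and −7 nS static conductances) and
implement soft winner-take-all.  Conduction delays are Gaussian with
mean distance/speed plus a 1.5 ms synaptic floor and 30% relative SD;
between-network axons conduct ten-fold faster (myelination).

Every memory pattern claims one MC per HC, non-overlapping.  Long-term
attractors are embedded *before* the task by offline Bayesian–Hebbian
training on synthetic assembly spike trains, then frozen.  The training
protocol is the package's own design (only its outcome is externally
constrained): all 16 patterns of each network are cued in shuffled order
for 200 ms each, separated by 9 s of silence, over 12 cycles, with a
reduced learning-rate factor (0.05) so the probability traces average
over several cycles.  Cued assemblies fire in synchronized population
bursts (40 Hz, 4 spikes per burst, 1.2 ms jitter) — attractor activation
in this family of models proceeds in gamma-like population cycles, and
the burst structure matters: conduction delays de-correlate the fast
co-trace across HCs but barely within an HC, which is what makes
within-HC attractor weights stronger than across-HC ones and gives
never-coactive patterns negative (disynaptic-inhibition) weights.  The
duty cycle (200 ms per ~147 s) sets the marginal activation probability
and thereby the weight amplitude; it was calibrated once so that the
mean single-connection EPSP of within-HC attractor weights, measured at
the resting potential with the first-spike release gain, sits at
0.72 mV — the biologically constrained amplitude this model family
reports — and was not revisited afterwards.  Tonic high-rate training
was rejected because it produces no within/across-HC differentiation.

The per-cell traces at the end of training initialize the
intrinsic-excitability biases; associative connections start from those
marginals with $P_{ij} = P_i P_j$, i.e. at exactly zero weight — the
task begins with no item–context associations.

## Task protocol

A trial is the serial stimulation (250 ms each, 200 ms apart) of a pair
of items while the current context assembly is continuously cued; all
pyramidal cells additionally receive zero-mean background bombardment
(two independent 470 Hz Poisson generators with opposing driving
potentials, ±1.5 nS), and cued assemblies an extra 340 Hz, +1.5 nS
drive.  The background is calibrated to keep the network near a
responsive state without spontaneous attractor transitions.  An item
becomes old-in-context upon its first presentation in a context.  The
model "selects" the new item when its trial-average assembly rate is at
least 15% below the pair-matched old item's; ties and silent trials
count as errors.  A hit triggers a 100 ms re-stimulation of the chosen
item followed, 250 ms later, by the 250 ms reward window.

The reference description shows the pairing structure but not a full
enumeration of encoding trials, so the generator uses the simplest
composition that satisfies every constraint: context-A presents its 8
items once each in 4 same-status pairs; context-B presents the
context-A items first, then the withheld items — which realizes the
Arrangement-1 recency ordering (new-in-A more recent than old-in-A) for
*every* admissible assessment pairing and keeps all pairs distinct
throughout the task.  Arrangement 2 re-activates the context-A items at
the end of the context-B block; the unbalanced variant presents the
withheld items twice in context B; the extra-context variant inserts a
context-C block with a random half of the items (assessment pairs whose
old item thereby becomes the more recent are tagged and excluded from
Arrangement-1 analysis); the reverse-rewarding variant keeps the
reference structure and only redirects reward to old-in-context
selections, repeatable per activation.  An independent validator walks
the expanded event list and re-derives statuses, recency predicates and
pair uniqueness for every generated schedule.

## Scaled-down profile

The full-scale model is faithful to the reference layout but takes hours
per session on one core, so the test suite and the directional behavioral
reproductions run a reduced profile: 4 HCs of 8 MCs per network, 10
pyramidal and 2 basket cells per MC, 8 items and 2–3 contexts, ~20 s
sessions at dt = 0.2 ms (the subthreshold-accuracy checks use 0.1 ms).
Shrinking the network cuts every in-degree several-fold, so per-cell
synaptic and intrinsic currents must be rescaled to stay in the
operating regime of the full model.  The profile raises the connection
probabilities (0.5 recurrent, 0.2 associative, with basket conductances
doubled), multiplies the learned within-network weights by 2.4 and the
associative gains by 16, scales the bias gain by 3 with the background
conductance raised to compensate the deeper resting bias, and raises the
specific cue by 1.8.  The intermediate-term probability-trace constant
is time-compressed to 5 s for the task (preloading keeps 30 s): a ~20 s
session stands in for a ~100 s one, and without the compression the
anti-correlation that builds disynaptic inhibition between a context and
its never-coactive items cannot develop within a session.

What the reduced model shows: old-in-context assemblies respond more
strongly than their paired new items (positive median rate difference),
recency synergy (Arrangement 2 above Arrangement 1), collapse of
performance when the associative disynaptic inhibition is severed, and
interference from an extra context.  What it does not show: the
reverse-rewarding deficit.  That effect is carried by the *distribution
of rewards* across items — a weight-channel phenomenon that at full
scale rides on many small (~percent-level) trace updates per event.  At
desk scale each item is coactivated with a context once or twice, so
per-event plasticity is necessarily coarse, and the recalibration that
reproduces the recency-synergy ordering places the readout in a regime
dominated by activity history (bias and augmentation), where the
reward-distribution effect is masked.  Configurations that recover the
reverse-rewarding deficit invert the recency synergy instead; the two
orderings were not simultaneously attainable in the reduced model, and
the package reports the reverse-rewarding comparison as it comes out.
More generally, passing directional checks at this scale demonstrates
that the mechanisms interact as described, not that the reduced model
reproduces full-scale percentages — those require the full profile.

The synthetic training trains and the Poisson stimulation emulate the
*statistics* that matter for the learning rule (marginal activation
probabilities, assembly co-activation, burst-scale synchrony,
conduction-delay structure); they do not emulate oscillatory network
feedback during training, neuromodulatory state, or trial-to-trial
behavioral variability of real animals, so quantitative agreement with
in-vivo recordings is out of scope throughout.

## Reproducibility and degenerate inputs

Every stochastic step (connectivity, delays, training trains, schedules,
background noise) draws from a named substream derived from one master
seed (`derive_seeds()`); identical configurations produce bit-identical
spike rasters.  Builders and generators refuse to run without a seed.
Degenerate cases are defined, not patched: trials with two silent
assemblies score as errors; coincident trace time constants are nudged
apart by 1e-12 in the exact propagators; the exponential upstroke
argument is clamped at +20 and a spike is declared at
$V_t + 10\Delta_T$, where the upstroke is already effectively vertical;
delays are floored at the 1.5 ms synaptic minimum and quantized to the
integration step by the delivery ring buffer, which reproduces stored
delays exactly.
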