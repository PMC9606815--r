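---
title: "A cortico-hippocampal model of sequence memory consolidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cortico-hippocampal model of sequence memory consolidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seqconsol` simulates systems-level consolidation of sequential memories in
a pair of coupled recurrent item networks: a fast-learning, fast-forgetting
hippocampus (HC) and a slow-learning, slow-forgetting cortex (CTX), in the
spirit of complementary-learning-systems theory. A sequence such as
A-B-C-D-E is experienced once or a few times during waking; what persists
long-term is decided offline, during simulated slow-wave sleep (SWS), when
salience-biased stochastic reactivations ("replays") of items re-express
the sequence in time-compressed form and gradually transfer it into the
cortical weight matrix.

## Activation dynamics

Each percept is represented by one rate neuron ("item") per region. An
item's activation $a_x \in [0,1]$ follows shunting (Grossberg-style)
dynamics in a recurrent competitive network,

$$\sigma_a \frac{da_x}{dt} = -\frac{a_x}{\tau_a} + (1 - a_x)E_x - a_x I_x,$$

so excitation drives $a_x$ toward 1, inhibition toward 0, and the bounds
can never be crossed in continuous time. The net excitation

$$E_x = \mu F_x + \gamma \sum_{y \neq x} w_{yx} a_y
      + \alpha \frac{a_x^m}{a_x^m + t_a^m}$$

combines feedforward drive ($F_x$ is the input register for CTX with
$\mu_c = 1$, and the corresponding cortical activation for HC with
$\mu_h = 2$), learned spreading excitation through directional weights
$w_{yx}$, and a sigmoidal self-excitation that ignites an item once it
passes roughly $t_a = 0.09$. Cortical items additionally receive rectified
hippocampal feedback $\zeta [h_x]^+$ — the pathway whose lesion models
hippocampal disconnection. Inhibition

$$I_x = \beta \sum_{y \neq x} a_y
      + \theta \frac{g_x^n}{g_x^n + t_h^n}$$

couples strong lateral competition ($\beta = 15$; at most one or two items
are meaningfully active at a time) with delayed self-inhibition through an
inactivation current $g_x$,

$$\sigma_g \frac{dg_x}{dt} = -\frac{g_x}{\tau_g} + (1 - g_x)[\kappa a_x],$$

which terminates prolonged activations: an ignited item is extinguished
after roughly a second of waking activity, making item activations
ephemeral pulses. The speed factor $\sigma_a$ is the wake/sleep switch:
$\sigma_{a,\text{wake}} = 2$ gives a 1.6 s activation time constant
(matching 2 s stimuli), $\sigma_{a,\text{sleep}} = 0.04$ a 32 ms one, so
the same connectivity replays a sequence inside a half-second UP state that
takes several seconds to recall awake. $\sigma_g$ is deliberately not
mode-switched; the inactivation current is a slow biophysical process.

## The causal learning rule

Directional weights $w_{xy} \in [0,1]$ exist only on instantiated links and
obey

$$\frac{dw_{xy}}{dt} = \eta \left\{ -\frac{w_{xy}}{\tau_w}
  + a_x (1 - w_{xy}) \left( \left[\dot a_y\right]^+
  - Q \left[-\dot a_y\right]^+ \right) \right\},$$

a rate-based causal rule: the link from $x$ to $y$ is potentiated while $x$
is active and $y$'s activation is *rising*, and depressed (by the fraction
$Q = 0.5$) while $y$ is falling. Forward associations in a sequence
therefore grow while reverse ones are eliminated; simultaneous
co-occurrences still associate because only half of the symmetric
depression survives. The hippocampus uses $\eta_h = 15$, the cortex
$\eta_c = 1.5$: one waking exposure writes a strong hippocampal trace while
the cortical copy stays weak.

Two readings of the printed decay constants are possible, and the package
exposes both (`decay_time_unit`, `decay_scaled_by_eta`). The default treats
$\tau_{w,h} = 1.5552 \times 10^9$ and $\tau_{w,c} = 3.73248 \times 10^{10}$
as milliseconds and keeps the decay term inside the $\eta$ brace exactly as
written, giving effective decay constants of $1.2$ days (HC) and $288$ days
(CTX) — i.e. decay to near-baseline over roughly ten days and two years
respectively. This is the only reading under which the model's sleep
behaviour is coherent: the hippocampal engram measurably fades between
nights (so nightly replays have something to "refresh", and an unreplayed
sequence is genuinely lost within two to three days) while the cortical
engram suffers only imperceptible decay over an experiment. With the
alternative reading (no $\eta$ on decay; 18-day hippocampal constant) the
hippocampus never forgets on the experimental timescale and competition
between memories has no teeth.

### Link instantiation

Links are created, at weight zero and in both directions, between any two
items of the same region whose activations are simultaneously above the
co-activation threshold — and only while external training input is being
presented. New structure is a property of experience; recall and sleep can
only strengthen or weaken existing links. The threshold defaults to 0.05.
This value was chosen by measuring the two co-activation regimes that occur
during training: temporally adjacent items genuinely overlap (the earlier
item's decaying pulse meets the next item's ignition at levels of about
0.056–0.069 in both regions), whereas non-adjacent items only ever share
residual tails (below about 0.03 even late in training, when strengthened
weights speed up ignition). A threshold of 0.05 separates the two regimes
throughout training, so the learned graph contains exactly the
adjacent-item chain plus its (weight-suppressed) reverse links. A
permissive threshold such as 0.01 instead instantiates skip-links (A→C,
B→D, ...) from residual tails; compressed sleep replays then pump those
shortcuts toward saturation, and cued recall eventually mis-orders items
(the shortcut delivers C before B by tens of milliseconds). Learning
long-range links between non-adjacent items is exactly the contextual
recall extension this item-based model does not attempt.

## Salience and sleep replays

Each item carries a salience trace, a leaky one-day moving average of its
waking cortical activation:

$$\frac{ds_x}{dt} = -\frac{s_x}{\tau_s} + \lambda a_x,
\qquad \tau_s = 86400 \text{ s},\ \lambda_\text{wake} = 1000,\
\lambda_\text{sleep} = 0.$$

Salience encodes recency and frequency of use; it is deliberately blind to
sleep activity, otherwise replayed items would amplify their own replay
probability in a runaway loop.

A night of SWS is a continuous block of slow-wave oscillations (default 50
cycles at 1 Hz, one 0.5 s UP state per cycle). At each UP-state onset one
item is drawn with probability $s_x / (\sum_y s_y + s_0)$, where the null
item's fixed salience $s_0 = 0.5$ absorbs the remaining mass (no replay
this UP state — the likely outcome when nothing has been experienced
recently). A non-null cue is pulsed into the cortical input register
(amplitude 0.2 for 12.5 ms; with the 1 ms integration step this is realized
as 12 steps) and the network then runs freely under sleep dynamics:
the cued cortical item ignites, drives its hippocampal counterpart, and the
stronger hippocampal chain races ahead, feeding each successive item back
to the cortex. Since any item can be cued, replays are typically
fragmentary — a cue at C replays C-D-E — which is why, over many nights,
the first link of a sequence (A→B) ends up the weakest: it is only
exercised when A itself is cued. Activations and inactivation currents are
reset to zero at every UP-state end; DOWN states carry no activity and are
applied as closed-form weight decay (numerically indistinguishable from
stepping an all-zero state, and twice as fast). Salience is decayed in
closed form over the whole block.

Time compression makes sleep learning efficacious: in a consolidated
network a full five-item replay completes in roughly 0.15–0.45 s, versus
4–7 s for the cued waking cascade (a compression factor of 10–30), so the
presynaptic item is still strongly active while its successor rises and the
cortical weight increment per exposure is much larger than during waking
training.

## Recall metrics

A recall test presents the cue in the input register (0.1 for 1.5 s) and
integrates — with learning and salience still on, since recall is itself an
experience — until every target item has crossed the cortical recall
threshold (0.01) or 30 s elapse. An item is recalled when its cortical
activation first crosses the threshold upward; simultaneous same-step
crossings are ordered by descending activation (a deterministic
tie-break). Recall accuracy is the percent of target items crossed in the
correct order, with credit ending at the first out-of-order or non-target
crossing; recall time is the cue-onset-to-final-crossing interval for fully
accurate recalls and the 30 s ceiling otherwise. The cue's own externally
driven crossing counts as its recall.

## Experiment protocol

Experiments are declarative day-level timelines (`experiment_spec()`,
YAML-configurable, six shipped presets). Within each simulated day, morning
tests run at hour 8, training at hour 9 (2 s per item, 5 ms inter-stimulus
interval, 60 s between trials), evening tests 60 s after training, and the
SWS block at hour 23; these wall-clock placements are package choices (no
canonical values exist) and they matter only through the one-day salience
decay and the ~1-day hippocampal weight decay between events. Two sequences
trained on the same day are trained as consecutive blocks in the listed
order. The intervals between events are fast-forwarded analytically:
transients are reset (activity has died out long before; the idle-gap
precondition), and weights and salience decay in closed form, which matches
brute-force Euler integration of the gap to better than $10^{-5}$ relative.
The replay cue draw is the only consumer of randomness, so a run is
bit-reproducible from its seed.

Typical problem sizes are deliberately small and mirror the presets: 5–10
items, 10 trials per training session, 4 nights of 50 UP states, and
20-seed replicates for stochastic replay-share estimates; a full
five-day experiment integrates a few times $10^5$ Euler steps and runs in
a couple of seconds (the stepping loop is compiled).

## Numerical choices

Forward Euler with a fixed 1 ms step everywhere; synchronous update order
per step: (1) excitation/inhibition and analytic derivatives from the
previous-step state, (2) weight update from the pre-update activations and
the analytic $\dot a$ (not a finite difference — this removes
$\Delta t$-order noise from the learning signal), (3) salience from the
pre-update cortical activations, (4) state update with clamping of $a$,
$g$, $w$ to $[0,1]$ (shunting bounds hold in continuous time; Euler can
overshoot under the strong sleep-mode inhibition). The hippocampal
feedforward uses the previous-step cortical activation, making the update
order-independent within a step. A pure-R reference implementation of the
same step (`step_network()`, `update_weights()`, `update_salience()`) is
the definitional surface; the test suite holds the compiled engine to it at
$10^{-12}$ over hundreds of steps.

## What passing tests do and do not show

The simulator reproduces, under its default parameters: the day-1
calibration (peak hippocampal forward weights above 75% of maximum,
cortical below 40%); elimination of reverse links at $Q = 0.5$; nightly
replay shares shifting toward the daily-practiced sequence (about
79/93/96% on nights 2–4 for the two-sequence schedule, against 74/94/98%
as the reference values); cortical independence when hippocampal learning
is disabled during sleep (day-5 recall survives severing the feedback);
and 10–30-fold replay time compression.

Two figure-level behaviours of the modelled system are *not* reproduced,
and the corresponding acceptance tests are left failing deliberately.
First, with hippocampus-to-cortex feedback lesioned from the start,
cortical weights should barely grow; here they gain ~0.02–0.03 per night
because the cued cortical item, which the mode-independent (slow)
inactivation current cannot extinguish within an UP state, holds its
successor at a small positive co-activation whose onset rise is
Hebbian-credited at every UP state. The increments compound and cross the
autonomous-ignition threshold on the fourth night. Second, under
competition from a more practiced sequence, the unpracticed sequence
should become unrecallable by day 3; here the first night's replays already
push its cortical weights past the autonomous-recall bifurcation, and each
successful daily test (recall being plastic) re-writes the hippocampal
trace, a self-sustaining loop. Both behaviours sit on knife-edge regime
boundaries of the published parameter set — small changes in the cortical
learning increment per UP state, or in the autonomous-ignition threshold,
move the system across them — and we chose to keep the equations and
constants faithful rather than bend any printed value to force the
qualitative outcome.

## Limitations

Items are single neurons, not distributed patterns; there is no synaptic
consolidation, overlap regularization or structural pruning (decayed links
persist at near-zero weight); sleep is a single SWS block per night with a
scheduling-only 1 Hz oscillation (no sharp-wave-ripple waveform, no REM,
no reverse replays, no quiet-wake replay); salience is pure
recency/frequency with no novelty, reward or neuromodulatory terms; and
recall is item-based, so sequences overlapping in an interior item
cross-talk at the junction (consolidating A-B-C-D-E and F-G-C-I-J yields
competing continuations after C), the known cost of having no contextual
long-range links.
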