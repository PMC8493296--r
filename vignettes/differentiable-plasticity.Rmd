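---
title: "Differentiable synaptic plasticity in spiking networks: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable synaptic plasticity in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

plasticsnn trains feedforward spiking networks in which the synaptic weights
*and* the rules that change synaptic efficacy during behaviour are learned
jointly by gradient descent. This vignette documents the model equations as
implemented, the tunable parameters and their defaults, the synthetic
benchmark and what it does (and does not) emulate, the numerical choices, and
the design decisions that were genuinely open.

## Neuron model

Neurons follow a discrete-time spike response model (SRM). For layer $l$ at
step $t$:

$$
a^{(l)}(t) = \sum_{k=0}^{K-1} \varepsilon(k)\, s^{(l-1)}(t-k), \qquad
u^{(l)}(t) = \big(W^{(l)} + \alpha^{(l)} \odot E^{(l)}(t)\big)\, a^{(l)}(t)
             + \sum_{m=1}^{K} \nu(m\!-\!1)\, s^{(l)}(t-m),
$$

with binary spikes $s^{(l)}(t) = \mathbf{1}[\,u^{(l)}(t) \ge \vartheta\,]$.
Choices and their reasons:

* **Kernels.** $\varepsilon(k) = e^{-k/\tau_s}$ (unit amplitude) and
  $\nu(k) = -\vartheta\, e^{-k/\tau_r}$, truncated exactly at $K$ taps.
  Defaults $\tau_s = \tau_r = 2$ steps, $K = 8$, $\vartheta = 1$, reset
  baseline $u_r = 0$. These are the canonical exponential SRM choices; the
  truncation point is where the kernel's contribution is practically nil
  ($e^{-3.5} \approx 0.03$).
* **Threshold semantics.** A neuron fires when $u \ge \vartheta$. Exact
  equality with the threshold is measure-zero in floating point, so the
  closed inequality is the standard discrete-time convention.
* **Reset.** The refractory kernel acts on the neuron's own spikes strictly
  before $t$: its leading tap is $-\vartheta$, so a spike at $t-1$ subtracts
  the full threshold from $u(t)$, which implements reset-by-overwrite to
  $u_r = 0$ while keeping the membrane a pure function of the last $K$
  spikes (the *stateless-kernel* formulation). This keeps the
  backpropagation-through-time graph depth per membrane value bounded by
  $K$.
* **Surrogate gradient.** The forward pass emits exact binary spikes; the
  backward pass substitutes the pseudo-derivative
  $\sigma'(u) = e^{-c\,|u - \vartheta|}$ with sharpness $c = 5$
  (an exponential, SLAYER-style family; a fast-sigmoid family is also
  provided). Gradient correctness is testable because this surrogate has an
  exact smooth antiderivative: running the network in "smooth mode" (the
  spike replaced by that antiderivative) yields a differentiable loss whose
  central finite differences must match the backpropagated gradients, for
  every parameter group — this is enforced in the test suite at
  $10^{-4}$ relative tolerance.

## Plasticity rules

A synaptic trace $E^{(l)}(t)$ (one entry per synapse, zero at episode start)
accumulates pre/post activity and contributes $\alpha \odot E$ to the
effective weight. Traces update every $\Delta\tau$ steps from spike rates
$r = (\text{spike count})/\Delta\tau$ over a tumbling (non-overlapping)
window, synchronized across layers; the linear-decay rule updates every step
from instantaneous spikes. After every update $E$ is clipped elementwise to
$[-C, C]$.

| rule | update |
|---|---|
| linear decay | $E' = (1-\eta)E + \eta\, \rho_{\text{post}} \rho_{\text{pre}}^\top$ |
| Oja | $E' = (1-\eta)E + \eta\,(r_{\text{post}} - E r_{\text{pre}})\, r_{\text{pre}}^\top$ |
| BCM | $E' = (1-\eta)E + \eta\, r_{\text{post}}\, r_\beta^\top$, $r_\beta = r_{\text{pre}} \odot (r_{\text{pre}} - (\phi + \psi))$, $\phi' = (1-\eta_\phi)\phi + \eta_\phi\, \omega(r_{\text{pre}})$ |
| NDP-Oja | Oja with $r_{\text{post}} \to M \odot r_{\text{post}}$, $M = W_m r_{\text{post}}$ |
| NDP-BCM | BCM with $r_{\text{post}} \to M \odot r_{\text{post}}$ |

* $\eta$ and $\eta_\phi$ are stored unconstrained and squashed through a
  sigmoid into $(0,1)$: the $(1-\eta)$ memory term is only a stable convex
  blend on that interval, and the reparameterization lets Adam move freely.
  Both start at $0.1$.
* $\Delta\tau = 10$ steps for the rate-based rules (the interval is not
  pinned by theory; 10 steps at the benchmark's cue length gives one update
  per cue), $\Delta\tau = 1$ with instantaneous spikes for linear decay.
* $C = 2$ bounds runaway traces without binding in practice (observed
  $|E| \lesssim 0.1$ on the benchmark).
* $\omega$ is the identity; the registry exists so other pre-activity
  functions can be added, but only the identity is exercised.
* A useful analytic anchor: in the scalar case with constant rates and no
  clipping, the Oja iteration contracts geometrically at rate
  $1 - \eta(1 + r_{\text{pre}}^2)$ to the fixed point
  $E^\ast = r_{\text{post}} r_{\text{pre}} / (1 + r_{\text{pre}}^2)$, and
  the BCM threshold follows the geometric series
  $\phi_k = r_{\text{pre}}(1 - (1-\eta_\phi)^k)$. Both closed forms are
  asserted to $10^{-12}$–$10^{-10}$ in the tests.

## The cue-association benchmark

The bundled T-maze task presents `n_cues` randomly sided cues as periods of
high spiking in side-specific 10-neuron input groups, then a delay, then a
decision period in which a third group fires; a fourth group spikes randomly
throughout. The correct decision is the majority side; reward is $+1/-1$.
Decisions are sampled from a binomial head whose log-odds are the difference
of the two output neurons' spike counts over the decision period (the
difference of counts is the minimal two-way softmax reading of log-odds, and
equal activity gives chance by symmetry).

Presets (all configurable):

* **Timing, full scale:** 7 cues × (20 on + 10 off), 120-step delay,
  40-step decision ≈ 370 steps, 64 hidden neurons.
* **Timing, scaled:** 3 cues × (10 + 5), 30-step delay, 20-step decision =
  95 steps, 32 hidden neurons. This is the preset used for routine runs,
  the test suite and the reproduction script: one training run to the
  halting criterion takes a few minutes on one CPU at these sizes.
* **Noise regimes:** low = {in-cue probability 0.5, stray 0.01, noise group
  0.05}; high = {0.35, 0.05, 0.15}. The exact probabilities are free
  choices; the high regime has strictly more stray spiking and strictly
  weaker cues, which is the defining ordering.

What the generator emulates: stochastic population cues, task-irrelevant
noise, a delay that exceeds the membrane memory by design (30 steps versus
$K = 8$), so the only path from cues to decision runs through the synaptic
traces. What it does not emulate: real sensory statistics (cue groups are
disjoint and homogeneous), trial-to-trial nonstationarity, or any
correlation structure between noise and cues. Passing tests therefore show
that trace-based memory and its gradients work as specified — not that the
method transfers to richer stimuli.

## Training

REINFORCE with the batch-mean reward baseline, backpropagation through time
over the full unrolled episode (traces reset each episode), and Adam
($\beta = (0.9, 0.999)$, global gradient-norm clip 1.0). After every
iteration the policy is evaluated on 100 fresh episodes with sampled
decisions; the reported loss is $-$accuracy and training halts at
loss $\le -0.97$. All randomness flows from one seed through named
sub-streams (init, env, policy, eval), so runs reproduce exactly.

**Benchmark configuration.** Two groups of magnitudes had to be chosen where
no principled value exists, and the choices matter:

* *Initialization.* Weights start at $N(0, (g/\sqrt{n_{\text{pre}}})^2)$
  with gain $g = 4$, sized so hidden neurons fire at roughly 0.1–0.2
  spikes/step during cues and output counts sit near the decision
  threshold — threshold units with too-small weights are silent and their
  surrogate gradients vanish. Plasticity coefficients start at
  $U(-0.3, 0.3)$ and the modulatory matrix at $U(-1, 1)/n_{\text{post}}$.
  The effective-weight perturbation $\alpha \odot E$ and the modulated
  write $M \odot r$ are each products of two learned factors; if both
  factors start near zero the learning signal for the whole plastic
  pathway is second-order small, and training provably stalls at chance
  (we verified this with supervised-gradient probes: with
  $\alpha \sim U(-0.01, 0.01)$ the task is not learned within any feasible
  budget, and a cross-entropy objective actively silences the output
  layer — a local minimum in which gradient noise is minimized by not
  spiking). `snn_network()` itself keeps small-magnitude neutral defaults;
  the benchmark entry points (`train_cue_task()`, `run_experiment()`) use
  the configuration above.
* *Optimizer.* lr $10^{-2}$, 50 episodes per batch (100 at full scale).
  Adam's per-coordinate normalization means the learning rate, not the raw
  gradient scale, sets the speed at which the plastic parameters grow; at
  $10^{-3}$ convergence needs several times more iterations than the
  budgets used here.
* *Decision-head conditioning.* The binomial head turns the output-count
  difference into log-odds, and with a 20-step decision window that
  difference can reach $\pm 20$. Two random-initialization pathologies
  follow, each freezing training at chance: a silent output layer (membrane
  far below threshold, surrogate derivatives $\approx e^{-c|u-\vartheta|}$
  effectively zero) and a ceiling-rate output layer, where any small
  count asymmetry saturates the logistic and the policy gradient
  $1 - p(\text{chosen})$ vanishes. The benchmark nets therefore (i)
  initialize the two output weight rows identically, so the count
  difference starts at exactly zero — maximal policy gradient, symmetry
  broken only by the row-asymmetric plasticity coefficients and modulatory
  weights — and (ii) calibrate the output-layer gain on a 16-episode probe
  batch so the initial decision-window firing rate is 0.2 spikes per
  neuron per step (`calibrate_decision_scale()`; a data-dependent
  initialization in the spirit of variance-normalizing schemes). Both are
  structural conditioning choices, not task knobs: they change where
  training starts, not the task, the dynamics, or the halting criterion.
* *Restarts.* Even well-conditioned runs show a characteristic REINFORCE
  take-off: accuracy sits at chance until the bilinear plastic readout
  (plasticity coefficients times modulatory weights) aligns with the
  cue-side signal, then converges within a few dozen iterations. The
  waiting time behaves almost memorylessly across initializations (roughly
  a 0.4 probability of take-off per 200 iterations at the scaled preset),
  so `train_cue_task()` re-initializes the network from a deterministically
  derived seed whenever no learning signal has appeared after
  `restart_after = 200` iterations — "no signal" meaning best accuracy
  below 0.75, safely above the ~0.68 running maximum that pure chance
  produces over hundreds of 100-episode evaluations. Restarts spend the
  same total iteration budget and keep the run bit-reproducible; they turn
  a per-attempt lottery into a high-probability procedure (four to seven
  attempts fit typical budgets).

With this configuration an NDP-Oja network reaches the halting criterion on
the scaled low-noise preset in roughly 150–250 iterations (a few minutes,
one CPU).

## Population coding and the control interface

For continuous-control use, scalars are encoded by place-coded populations:
Gaussian tuning curves with equally spaced centers over the clip range,
width 1.5× the center spacing, peak firing probability 0.8 and a floor
probability $\vartheta_{\min} = 0.02$ per neuron per step; each neuron draws
an independent Bernoulli spike each step. Actions are decoded from
positive/negative sub-populations (defaults 100 neurons per sign, 50-step
integration interval): the signed spike count normalized by its maximum, so
the decoded value is bounded by construction. An optional diagonal-Gaussian
head with learned log-standard deviations (initialized at $-0.5$ for
moderate exploration) adds action variance.

The damped point-mass environment stands in for a physics simulator behind
the conventional reset/step contract: per dimension
$v' = (1 - d f)v + a$ with reward $\sum v' - c\|a\|^2$, damping $d = 0.1$,
energy cost $c = 0.05$, friction coefficient $f$ exposed so friction noise
is meaningful. Its closed forms (terminal velocity $a/(df)$, optimal
constant action $1/(2cdf)$) anchor the tests. Noise models are exactly
observation $x + z$, action $a(1+z)$, and per-episode friction $f(1+z)$,
$z \sim N(0, \sigma^2 I)$; at $\sigma = 0$ every operator is the identity
and the noise-response ratio is exactly 1. The clipped-ratio (PPO)
surrogate objective is provided for control training
(clip 0.2, advantage normalization); a full locomotion training loop is out
of scope here, and noise-response evaluation runs on the spiking controller
directly.

## Numerical and engineering choices

* **Gradients.** R has no reverse-mode autodiff, so the package carries a
  minimal tape engine: each array operation appends a node (value, parents,
  pullback) and the backward sweep walks the tape in reverse. Two
  interchangeable op tables (taped / plain arrays) let the same forward
  code serve training and evaluation, and their agreement is a tested
  invariant.
* **Two forward paths.** The per-step path is the reference: one node per
  layer per time step, able to record membrane/response buffers and trace
  series. The chunk-fused path exploits the fact that traces only change at
  rate-window boundaries: dynamics between boundaries become one node per
  layer per window, with the in-window time loop walked inside the node's
  pullback and the plastic membrane term reduced to one small matrix
  product per episode per window. The chunked path requires
  $\Delta\tau \ge K$ (a window must contain the full kernel history of its
  successor) and falls back to the per-step path otherwise (so the
  linear-decay rule, with $\Delta\tau = 1$, always uses the reference
  path). Values and gradients of the two paths agree to machine precision
  on every rule; the suite enforces this.
* **Batching.** Episodes of one batch share their length, so the whole
  batch advances as matrices; per-episode trace matrices are stored as a
  single `[batch × n_post, n_pre]` block.
* **Degenerate inputs.** Zero input with zero initial state produces no
  spikes at any layer; empty batches and shape mismatches raise typed
  validation errors; probabilities and interval lengths are validated at
  spec construction.

## Problem sizes used by the tests and the reproduction script

The test suite trains at the scaled preset only. The rule-contrast and
spike-rate comparisons train each rule once (seed 1) under a shared cached
grid with an identical 400-iteration budget; the halting-criterion and
noise-regime checks reuse and extend that grid; the remaining criteria
(oracle equivalence, closed forms, gradient integrity, noise-model
exactness) are sub-second property checks. The reproduction script trains
one scaled NDP-Oja network with a 1400-iteration budget (seven restart
windows). At these sizes the observed outcomes are: NDP-Oja and NDP-BCM
reach the halting criterion (roughly 100-300 iterations when an attempt
takes off), the high-noise preset halts about as fast as the low-noise one,
DP-BCM halts in some attempts, and DP-Oja and DP-Linear do not learn within
these budgets — at this reduced scale their fixed Hebbian write (no learned
modulatory gate) leaves the decision readout without a usable gradient
path, so the rule-contrast and firing-rate comparisons involving them fail
honestly rather than being relaxed. Full-scale (64-neuron, 370-step)
training works through the same entry points (`scale = "full"`) but takes
correspondingly longer and larger batches.

## Known limitations

* Feedforward plasticity only: no recurrent self-connections, no
  spike-timing (pairwise-timing) kernels, no calcium-based models.
* The scaled benchmark shortens the paper-scale task; iterations-to-halt at
  full scale are not calibrated against the scaled preset.
* The chunked path's speed advantage disappears when $\Delta\tau < K$.
* Policy-gradient training of the continuous-control pipeline is provided
  as building blocks (losses, encoders, controller), not as a turnkey
  locomotion trainer.
* REINFORCE with a mean baseline is high-variance; the iteration counts
  reported by `compare_rules()` vary noticeably across seeds.
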