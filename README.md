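# plasticsnn

Differentiable synaptic plasticity for spiking neural networks, in R.

Most trained spiking networks freeze their synapses after training. This
package implements the alternative: feedforward spike-response-model (SRM)
networks whose weights **and** plasticity rules are optimized jointly by
surrogate-gradient backpropagation through time, so the synapses keep
adapting *within* an episode. It is aimed at computational-neuroscience and
neuromorphic-learning researchers who want a small, fully tested reference
implementation of learned Hebbian/neuromodulated plasticity with exact,
finite-difference-verified gradients.

## The model

Membrane dynamics per layer (discrete time, binary spikes):

```
a(t) = sum_k eps(k) s_pre(t-k)                  spike response (K-tap kernel)
u(t) = (W + alpha ⊙ E(t)) a(t) + sum_m nu(m-1) s(t-m)
s(t) = 1[u(t) >= theta]
```

The synaptic trace `E(t)` starts at zero each episode and evolves under one
of five differentiable rules, updated every `delta_tau` steps from spike
rates `r` and clipped to `[-C, C]`:

* **DP-Linear-Decay** `E' = (1-eta) E + eta rho_post rho_pre^T`
* **DP-Oja** `E' = (1-eta) E + eta (r_post - E r_pre) r_pre^T`
* **DP-BCM** `E' = (1-eta) E + eta r_post r_beta^T`,
  `r_beta = r_pre ⊙ (r_pre - (phi + psi))`,
  sliding threshold `phi' = (1-eta_phi) phi + eta_phi r_pre`
* **NDP-Oja / NDP-BCM** the same with the post-synaptic term gated by a
  learned neuromodulatory signal `M = W_m r_post`

`eta`, `eta_phi`, `psi`, `W_m`, `alpha` and `W` are all trained by gradient
descent; spikes are exact on the forward pass and use an exponential
surrogate derivative on the backward pass. Because R has no reverse-mode
autodiff, the package ships a minimal tape engine whose gradients are
validated against central finite differences of a smooth-mode loss for every
parameter group.

Included benchmarks: the noisy cue-association T-maze (random sided cues,
delay, decision period, +1/-1 reward, low/high noise regimes), place-coded
population encoders and positive/negative sub-population action decoding, a
binomial decision head and diagonal-Gaussian policy head, REINFORCE and
clipped-ratio (PPO) losses, Gaussian observation/action/friction noise
models, and a damped point-mass control environment behind a pluggable
reset/step interface.

## Worked example

Train a neuromodulated-Oja network on the scaled T-maze until it reaches
97% decision accuracy:

```r
library(plasticsnn)

task <- cue_task_spec("low", "scaled")   # 3 cues, 95-step episodes, 40 inputs
fit  <- train_cue_task(train_config(seed = 1), task, rule = "ndp_oja")
fit
glance(fit)
tail(tidy(fit), 3)
```

Output of this exact call (seed 1):

```
#> <cue_training> ndp_oja | 155 iterations | halted (criterion met) | best accuracy 0.980
#> # A tibble: 1 x 7
#>   rule    iterations halted best_loss best_accuracy final_accuracy hidden_rate
#>   <chr>        <int> <lgl>      <dbl>         <dbl>          <dbl>       <dbl>
#> 1 ndp_oja        155 TRUE       -0.98          0.98           0.98       0.182
#> # A tibble: 3 x 8
#>   iteration accuracy  loss train_accuracy mean_reward pg_loss hidden_rate train_hidden_rate
#>       <dbl>    <dbl> <dbl>          <dbl>       <dbl>   <dbl>       <dbl>             <dbl>
#> 1       153     0.86 -0.86           0.88        0.76 -0.276        0.179             0.178
#> 2       154     0.96 -0.96           0.94        0.88 -0.120        0.180             0.181
#> 3       155     0.98 -0.98           0.98        0.96 -0.0108       0.182             0.183
```

`accuracy` is the fraction of correct decisions over 100 fresh episodes
(decisions sampled from the binomial head), `loss = -accuracy` is the
halting metric (training stops at -0.97), and `hidden_rate` is mean hidden
spikes per neuron per step. A non-plastic network (`rule = "none"`) stays at
chance on this task: with a 30-step delay and an 8-tap membrane kernel, the
only route from cues to decision runs through the synaptic traces.

`autoplot(fit)` draws the accuracy and hidden-rate histories, and
`compare_rules()` tabulates iterations-to-halt, accuracy and hidden rates
across rules.

The command-line runner wraps the same functions:

```sh
inst/cli/plasticsnn run --rule ndp_oja --seed 1 --out runs/demo
inst/cli/plasticsnn compare --rules dp_oja,ndp_oja --out runs/cmp
inst/cli/plasticsnn evaluate-noise --seed 1 --out runs/noise
inst/cli/plasticsnn dump-episode --seed 4 --out runs/episode
```

`run` writes `metrics.csv`, a `params.json` snapshot, spike rasters of one
episode in `(time_step, neuron_index)` event-list form, and a manifest with
the resolved configuration and a content hash.

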