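# lifsorn

A self-organizing recurrent spiking network (LIF-SORN) model of sequence
learning in primary visual cortex, with the full simulation and analysis
pipeline of the cue-triggered replay experiment, in R.

## The science

Visual cortex can learn a repeated spatio-temporal stimulus: after
conditioning with a light spot swept across the retinotopic map, a brief
flash at the sequence's start point evokes spiking that partially replays
the trained sequence. `lifsorn` implements a spiking-network account of
this: a sheet of noisy conductance-based leaky integrate-and-fire neurons
($N^E = 1000$, $N^I = 200$ on 2500 × 1000 µm) whose recurrent excitatory
connectivity is shaped online by five interacting plasticity mechanisms —

* **STDP**: asymmetric exponential window
  ($A_+ e^{-\Delta t/\tau_+}$ for pre-before-post,
  $A_- e^{\Delta t/\tau_-}$ otherwise; $A_+\tau_+ = -A_-\tau_-$),
  nearest-neighbour pairing on spike *arrival* times,
* **STP**: presynaptic facilitation/depression $u, x$ with effective
  transmission $W\,u\,x$,
* **synaptic normalization**: each neuron's summed incoming excitatory
  weight is held at a boundary-corrected target, once per second,
* **structural plasticity**: distance-kernel growth of new synapses
  ($\sim\!6000$ candidates/s at weight $10^{-3}$) and pruning below
  $10^{-4}$, which makes the connection fraction settle at the kernel's
  volume fraction $2\pi\sigma_c^2/A \approx 0.1$,
* **intrinsic plasticity**: per-neuron threshold adaptation
  $V_T \mathrel{+}= \eta (N_{spikes} - r_{target}\Delta t)$ pinning rates
  at 3 Hz.

The experiment protocol (growth → test → train with a moving spot →
test), multi-electrode-style recording clusters A–H, and the analysis
layer (Gaussian-kernel cluster rates, Spearman replay scores,
cross-correlograms, spontaneous transition matrices, recall speed, match
persistence, weight→PSP conversion) are all included. The integration
loop is C++ (Rcpp); every result comes back as a tidy tibble, fitted
comparisons have `tidy()`/`glance()` methods, and each result type has a
plot function.

## A worked example

Grow a reduced network (100 excitatory neurons on the full-size sheet,
growth rate rescaled accordingly) under noise only, and look at the
self-organization:

```r
library(lifsorn)

net <- make_mini_network(n_exc = 100, scale = 1, seed = 1)
sim <- simulate_network(net, 60000, seed = 2)   # 60 s of model time
tail(sim$trace[, c("time_ms", "cf", "mean_weight", "rate_exc", "rate_inh")], 3)
#>   time_ms     cf mean_weight rate_exc rate_inh
#> 1   58000 0.0833       0.799     3.57     21.8
#> 2   59000 0.0839       0.793     3.58     22.0
#> 3   60000 0.0877       0.759     3.24     22
```

The E-to-E connection fraction (`cf`) has risen from zero and levelled
off near 0.1 — the distance kernel's volume fraction — while intrinsic
plasticity holds the excitatory rate near its 3 Hz target; the mean
synaptic weight is set by the normalization budget. The replay analysis
runs on any spike table; on a scripted sequence with known ground truth:

```r
cl <- build_clusters(net$neurons)
sp <- scripted_sequence_spikes(cl, n_trials = 5, separation_ms = 55)
replay_scores(replay_times(sp, clusters = cl))
#> # A tibble: 5 × 4
#>   phase trial   rho n_clusters
#>   <chr> <int> <dbl>      <int>
#> 1 test1     1     1          5
#> 2 test1     2     1          5
#> ...
```

Every trial scores a perfect Spearman correlation of 1 between cluster
firing times and positions, as constructed. A full experiment is one
call, `run_experiment(net, sorn_protocol("main"), seed)`, returning
annotated spikes, per-second connectivity traces and phase-boundary
weight snapshots; `training_weight_change()` then shows the
stripe-like connectivity (forward synapses strengthened, backward ones
weakened) that training imprints.

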