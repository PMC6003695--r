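---
title: "The LIF-SORN model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The LIF-SORN model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `lifsorn`, the choices we
made where the model description leaves room, and what the reduced test
networks can and cannot show. It is the reference for every tunable
parameter; `sorn_params()` carries the same defaults in code.

## The network

The model is a self-organizing recurrent network (SORN) of leaky
integrate-and-fire neurons standing in for a small patch of layer 5 rodent
cortex: `n_exc = 1000` excitatory and `n_inh = 200` inhibitory neurons
placed uniformly at random on a 2500 x 1000 um sheet. Membrane dynamics are
conductance-based,

$$\tau \frac{dV}{dt} = -(V - E_L) - (g_e + g_{ext})(V - E_e) - g_i(V - E_i)
  + \text{noise},$$

with resting potential $E_L = -60$ mV, membrane time constant $\tau = 20$
ms, reversal potentials $E_e = 0$ mV and $E_i = -80$ mV, and dimensionless
conductances that decay exponentially with $\tau_e = 3$ ms (excitatory and
external) and $\tau_i = 5$ ms (inhibitory) and jump by the synaptic weight
on each delayed spike arrival. A spike is fired when $V$ crosses the
threshold — fixed at $-48$ mV for inhibitory neurons, adaptive for
excitatory ones — after which $V$ is clamped to the reset potential
($-70$ mV excitatory, $-60$ mV inhibitory) for an absolute refractory
period.

Connectivity is distance-dependent: every ordered pair carries a Gaussian
kernel weight $\exp(-d^2/2\sigma_c^2)$ with $\sigma_c = 200$ um. The
E-to-I, I-to-E and I-to-I classes are wired once at construction (fractions
0.1, 0.1 and 0.5 of ordered pairs, weights 0.15, 0.4 and 0.4, axonal delays
1, 2 and 2 ms) and never change. Recurrent E-to-E synapses (delay 3 ms)
start absent and are governed by the five plasticity mechanisms below.

### Membrane noise

The model description gives the noise term as $\sigma \xi(t)$ with
$\sigma = 16$ mV but does not pin down the discretization. We integrate an
Ornstein-Uhlenbeck reading: per step each neuron receives an independent
increment $\sigma \sqrt{2\,\Delta t/\tau}\; \mathcal N(0,1)$, which makes
$\sigma$ the *stationary standard deviation* of the free membrane
potential. We also implemented and rejected the literal reading
$\sigma \xi(t)/\tau$ (stationary SD $\sigma/\sqrt{2\tau/\Delta t \cdot
\Delta t} \approx 2.5$ mV): with fluctuations that small the network
sits silent until the adaptive thresholds creep down and then discharges
in synchronized avalanches — it never reaches the asynchronous-irregular
regime that the model is supposed to inhabit. Under the OU reading the
network fires asynchronously (pairwise count correlations centred on 0)
and irregularly (interspike-interval CV near 1) at the intrinsic
plasticity target rate, which is the regime the analysis assumes. The
noise SD is configurable (`neuron$sigma_noise`).

### Refractory period

The ISI statistics of the model show a refractory distortion but its
duration is not stated anywhere we could find; we use an absolute
refractory period of 5 ms (`neuron$t_refrac`), the value used by the
predecessor network of the same family. At a 3 Hz operating point its
influence on any reported statistic is minor (it shaves the ISI CV by a
few percent).

### Initial thresholds

Excitatory thresholds start at $-48$ mV, the inhibitory value, and are
taken over by intrinsic plasticity from the first step. Under the OU noise
the network fires immediately and the choice is forgotten within tens of
seconds; it is exposed as `neuron$V_T_E_init`.

## The five plasticity mechanisms

All act on E-to-E synapses only; the other classes are static after a
one-off normalization.

**Short-term plasticity (STP).** Each excitatory neuron carries a
facilitation variable $u$ (baseline $U = 0.04$, time constant $\tau_f = 2$
s) and a depression variable $x$ (baseline 1, $\tau_d = 0.5$ s) governing
all of its outgoing E-to-E efficacy. When a spike arrives at the synapses
(spike time + 3 ms), the transmitted weight is $W\,u(t^-)\,x(t^-)$, then
$u \mathrel{+}= U(1-u)$ and $x \mathrel{-}= x\,u$. At the 3 Hz operating
point the periodic steady state is $u^* \approx 0.21$, $x^* \approx 0.82$,
so a typical synapse transmits about 17% of its stored weight
(`stp_steady_state()`).

**Spike-timing dependent plasticity (STDP).** Asymmetric exponential
window, $A_+ = 4.8\times10^{-2}$, $\tau_+ = 15$ ms for pre-before-post and
$A_- = -2.4\times10^{-2}$, $\tau_- = 30$ ms for post-before-pre, evaluated
between postsynaptic spike times and presynaptic *arrival* times, with
nearest-neighbour pairing: each post spike pairs with the most recent
arrival, each arrival with the most recent post spike. The window is
balanced ($A_+\tau_+ = -A_-\tau_-$), so uncorrelated firing produces no
first-order drift (the exact finite-rate residual is derived and tested in
the suite). Weights are floored at 0. Tie-break at coincident events: the
window is zero at $\Delta t = 0$; a post spike coinciding with an arrival
pairs with the *previous* arrival (the coincident one cannot have caused
it), while the arrival pairs with the coincident post at zero effect.
Both still update the pairing memories.

**Synaptic normalization (SN).** Once per simulated second each excitatory
neuron's incoming E-to-E weights are rescaled so their sum equals

$$W_{total}(n) = \underbrace{0.1}_{\text{target CF}} \times N_E \times
  \underbrace{0.8}_{\text{mean strength}} \times b(n),$$

where $b(n)$ is the mass of a unit Gaussian of width $\sigma_c$ centred on
the neuron that falls inside the sheet (`boundary_factor()`, exact
separable closed form). Without $b(n)$, border neurons concentrate the
same budget on fewer synapses and seed activity waves starting at the
corners. The fixed classes are normalized the same way once before the
simulation starts, using their own insertion weights as mean strength.

**Structural plasticity (SP).** Once per second, a Gaussian number of
candidate synapses (mean and SD 6000 at full size; rounded, clamped at 0)
is drawn from the distance kernel over *all* ordered excitatory pairs;
candidates that already exist yield nothing, accepted ones are inserted at
$10^{-3}$. Pruning then removes every synapse strictly below $10^{-4}$.
The candidate pool deliberately includes existing pairs: growth then
self-limits as each neuron's kernel neighbourhood saturates, and the
connection fraction plateaus at the kernel's effective volume fraction

$$\frac{2\pi\sigma_c^2}{\text{width}\times\text{height}}
  = \frac{2\pi \cdot 200^2}{2500 \cdot 1000} = 0.1005,$$

which is exactly the connection fraction the full model is supposed to
reach. We first implemented the alternative reading — keep drawing until
the requested number of *new* synapses has been placed — and found that
realized growth then never slows down and the connection fraction
equilibrates near 0.25 instead of 0.1; the saturating reading is the one
consistent with the model's stated behaviour, and the coincidence of the
kernel volume fraction with the target CF is too exact to be accidental.
Within one call, candidates are independent draws; only the exact ordered
pair is blocked, so antiparallel synapses can coexist.

**Intrinsic plasticity (IP).** Every step, every excitatory threshold
moves by $\eta(N_{spikes} - h)$ with $\eta = 0.1$ mV and
$h = r_{target}\Delta t = 3\times10^{-4}$, pinning each neuron's long-run
rate to $r_{target} = 3$ Hz. In a noise-only run the population mean
settles within a few tens of seconds and stays at the target throughout.

### Update order

Within a 0.1 ms step: (1) Euler membrane update plus noise; (2) spike
detection after the update, reset, refractory; simultaneous crossings all
fire (delays $\geq$ 1 ms make within-step ordering irrelevant); STDP
potentiation on the detected spikes; (3) spike enqueueing into per-class
delay rings; (4) due deliveries, with the STP factor read before the jump
and STDP depression at arrival; (5) external Poisson input; (6) once per
simulated second, free-running from $t = 0$: SP growth, SP pruning, then
SN — newborn synapses are normalized immediately. Conductances decay by
the exact factor $e^{-\Delta t/\tau_{syn}}$ for stability. State carries
across calls exactly, except that deliveries still in the $\leq 3$ ms
delay ring when a call ends are dropped; experiments therefore run as a
single engine call, and the relaxation phases make the effect of any
manual phase split negligible.

## Stimulus and protocol

A stimulus block drives each excitatory neuron with `n_input = 100`
superposed Poisson trains whose rate is a super-Gaussian bump
$r_{max}\exp(-(d/\alpha)^\beta)$ of the distance $d$ to the spot centre
($r_{max} = 50$ Hz, $\alpha = 150$ um, $\beta = 4$); input spikes enter
the external conductance with jump $W_{FF} = 0.04$. A *sweep* moves the
centre linearly from $(375, 500)$ to $(2125, 500)$ um at $v_{spot} = 4$
um/ms (437.5 ms); a *cue* holds it at one point for 100 ms. The bar
variant's spatial profile is not specified by the model description; we
flash a bar whose cross-section equals the spot's, using the distance to
the start-goal segment, for the cue duration of 100 ms.

The main experiment runs growth 400 s (no input), test 100 s (50 cue
trials, one per 2 s), relax 10 s, train 200 s (100 sweeps), relax 10 s,
test 100 s. Variants move the cue (mid point, goal point), remove the test
input entirely (spontaneous activity), triple the second test phase
(persistence), shift the training trajectory 300 um orthogonally, or train
with bar or spot flashes. Recording clusters A-H are circles of radius 100
um with centres equidistant on the start-goal line, the outermost touching
the endpoints; replay metrics act on pooled cluster spikes. Whether the
two test phases share a stimulus seed is not specified; each phase uses
independent draws from the experiment's seed.

## Analysis conventions

Cluster rates are pooled spikes convolved with a unit-mass Gaussian kernel
of width $\tau_{rate} = 50$ ms, sampled on a 1 ms grid (decimation from
the 0.1 ms simulation grid changes peak times by less than half a
millisecond, negligible against $\tau_{rate}$). A cluster's firing time in
a trial is the first strict local maximum of its rate curve within 0-500
ms after cue onset; plateaus resolve to their midpoint; clusters without a
peak are dropped from the trial, and trials with fewer than two firing
clusters are dropped from score distributions (rank correlation is
undefined otherwise). Replay is scored by the Spearman correlation between
firing times and cluster positions along the stimulus axis (reversed axis
for goal cues), with average-rank ties. Before/after distributions are
compared by difference of means and a two-sample Kolmogorov-Smirnov test,
pooling trials (and instances where several are run); instance-level means
feed Wilcoxon-type comparisons.

Cross-correlograms bin pooled cluster spikes at 10 ms over the 0-500 ms
window, correlate counts at lags up to ±250 ms, pool by cluster distance,
and min-max normalize before/after/difference independently per distance
group; the bin width is not stated by the source analysis and is exposed
as an argument.

Spontaneous transition probabilities use all local rate maxima (strict, on
the sampled grid, no amplitude threshold; plateau runs collapse to their
midpoint; simultaneous maxima of different clusters are ordered by cluster
index, which at 1 ms resolution essentially never matters) merged into one
label sequence, and first-order transition counts normalized per source.

Recall speed is the OLS slope of cluster centre position against firing
time for trials with $\rho > 0.9$. A match (persistence analysis) is a
trial with $\rho > 0.6$; the change in match percentage is computed per
60 s bin of the post-training test phase against the whole pre-training
phase.

**Weight-to-PSP conversion.** The derivation used by the original
analysis is in an appendix we do not have. `weight_to_psp()` uses the
closed-form peak of the membrane equation's response to a single
conductance transient, linearized at rest:
$\Delta V_{peak} = w\,(E_{rev} - E_L)\,
\frac{\tau_s}{\tau-\tau_s}\!\left[ r^{-\tau_s/(\tau-\tau_s)} -
r^{-\tau/(\tau-\tau_s)}\right]$ with $r = \tau/\tau_s$ (the
$t\,e^{-t/\tau}$ limit when $\tau_s \to \tau$), validated against direct
single-spike simulation (agreement within the linearization error, under
2% at physiological amplitudes). For the population EPSP summary the
transmitted E-to-E weight is the stored weight times the STP steady-state
factor $u^*x^* \approx 0.17$ at the 3 Hz target: without any STP factor
the mean EPSP would be about 5 mV and with the rest-state factor $U = 0.04$
about 0.2 mV, both far outside the sub-millivolt range the conversion is
known to produce, while the steady-state factor lands in it. This is
documented as the package's own convention (`psp_summary()`).

## Reduced networks and what the tests show

`make_mini_network()` scales the sheet by $\sqrt{n_{exc}/1000}$
(preserving density) and the SP growth rate by $(n_{exc}/1000)^2$
(preserving the growth-to-pair-count ratio). Note that shrinking the sheet
raises the kernel volume fraction $2\pi\sigma_c^2/A$ above 0.1, so the
connection-fraction plateau of a shrunk-sheet network is higher than the
full model's; studies of the CF equilibrium itself use `scale = 1` (full
sheet, reduced density), which preserves the kernel fraction and hence the
0.1 plateau. For stimulus experiments the geometry must stay full-size, so the
test suite uses `n_exc = 500` on the full sheet with growth scaled by
0.25: half density halves cluster occupancy (~6 neurons) and all synapse
counts, which roughly doubles the sampling noise of every cluster
statistic.

The suite's experiment battery runs this half-density network through
shortened phases — growth 250 s, tests 60 s (30 trials), training 100 s
(50 sweeps) — chosen once as the smallest sizes at which the connection
fraction has plateaued before testing begins and each phase still contains
enough trials for distribution comparisons. At this scale the
training-induced stripe connectivity is detected robustly as the *paired*
weight change of adjacent-cluster synapses (`training_weight_change()`);
raw forward-vs-backward means at a single time point are dominated by
which few synapses happen to exist in a given instance. The replay-shift
effect itself (a few hundredths of Spearman correlation at full scale) is
at the edge of resolution of three half-density instances; the suite
checks the direction of the pooled shift and its contrast against the
goal-cue control rather than per-instance significance. Full-scale, 20-
instance reproduction of the headline numbers is a multi-hour computation
and is deliberately not part of the default test run.

Synthetic fixtures (`scripted_sequence_spikes()`) construct cluster bursts
with known order, spacing and jitter; every analysis metric is tested to
reproduce their ground truth exactly. The fixtures make no attempt at
biological realism — no background activity, no rate adaptation — so they
validate the analysis layer, not the network model.

## Known limitations

* Single-compartment neurons, class-homogeneous purely axonal delays; no
  plasticity on connections involving inhibitory neurons, so inhibition is
  unspecific.
* The bar stimulus profile and the refractory duration are our documented
  choices, not the source model's.
* The PSP conversion is a stand-in for an unavailable derivation; its
  absolute scale (not its weight-dependence) carries that uncertainty.
* In-flight synaptic deliveries are dropped at engine-call boundaries
  (≤ 3 ms of conductance input); run experiments as one call.
* `weighted_sample_noreplace`-based initial wiring is exact, but the
  engine's structural growth draws candidates with replacement within one
  second; at the default rates duplicate candidates are rare.
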