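#' Short-term plasticity: relaxation between spikes
#'
#' Per presynaptic excitatory neuron, the facilitation variable `u` relaxes
#' towards its baseline `U` with time constant `tau_f` and the depression
#' variable `x` towards 1 with time constant `tau_d` (exact exponential
#' update over an interval `dt` without spikes).
#'
#' @param u,x facilitation/depression state (vectors).
#' @param dt elapsed time, ms.
#' @param stp list with `U`, `tau_f`, `tau_d` (see [sorn_params()]).
#' @return list with relaxed `u` and `x`.
#' @examples
#' stp_decay(0.08, 1, dt = 2000)  # u halfway back to U after one tau_f
#' @export
stp_decay <- function(u, x, dt, stp = sorn_params()$stp) {
  stopifnot(dt > 0)
  list(u = stp$U + (u - stp$U) * exp(-dt / stp$tau_f),
       x = 1 + (x - 1) * exp(-dt / stp$tau_d))
}

#' Short-term plasticity: presynaptic spike arrival
#'
#' Applied when a presynaptic spike arrives at the synapse (spike time plus
#' the E-to-E axonal delay). The effective transmitted weight is
#' `W * u(t-) * x(t-)`, read before the state jumps; then facilitation jumps
#' by `U * (1 - u)` and depression by `-x * u` (both evaluated at the
#' pre-jump state).
#'
#' @inheritParams stp_decay
#' @return list with `eff_factor` (`u(t-) * x(t-)`) and the post-jump
#'   `u`, `x`.
#' @examples
#' stp_on_presyn_spike(0.04, 1)  # from rest: eff 0.04, then u=.0784, x=.96
#' @export
stp_on_presyn_spike <- function(u, x, stp = sorn_params()$stp) {
  eff <- u * x
  list(eff_factor = eff,
       u = u + stp$U * (1 - u),
       x = x - x * u)
}

#' Asymmetric exponential STDP window
#'
#' Weight change for a single pre/post pairing as a function of
#' `dt = t_post - t_pre_arrival` (ms), where the presynaptic time is the
#' *arrival* time at the synapse (spike time + E-to-E delay):
#' `A_plus * exp(-dt/tau_plus)` for `dt > 0`,
#' `A_minus * exp(dt/tau_minus)` for `dt < 0`, and 0 at `dt = 0`.
#' With the default amplitudes the window is balanced:
#' `A_plus * tau_plus + A_minus * tau_minus = 0`.
#'
#' @param dt post-minus-pre-arrival time difference(s), ms.
#' @param stdp list with `A_plus`, `A_minus`, `tau_plus`, `tau_minus`.
#' @return weight change(s), dimensionless.
#' @examples
#' stdp_window(c(-30, 0, 15))
#' @export
stdp_window <- function(dt, stdp = sorn_params()$stdp) {
  ifelse(dt > 0, stdp$A_plus * exp(-dt / stdp$tau_plus),
         ifelse(dt < 0, stdp$A_minus * exp(dt / stdp$tau_minus), 0))
}

#' Apply nearest-neighbour STDP to a recorded spike stream
#'
#' Replays a spike table through the incremental nearest-neighbour pairing
#' rule: on each postsynaptic spike, every incoming synapse is potentiated
#' against the most recent presynaptic *arrival* (pre spike + `delay_ee`);
#' on each presynaptic arrival, every outgoing synapse is depressed against
#' the most recent postsynaptic spike. Weights are floored at 0. Coincident
#' events (`dt = 0`) contribute nothing but still update the pairing
#' memories.
#'
#' This is the same rule the simulation engine applies online; it is exposed
#' so weight changes can be recomputed from a recorded `SpikeRecord`.
#'
#' @param spikes tibble with `time_ms` and `neuron_id` (excitatory ids).
#' @param synapses tibble with `pre`, `post`, `weight` (E-to-E rows).
#' @param params a [sorn_params()] object (uses `stdp` and `delay_ee`).
#' @param t_end end of the replayed interval, ms: presynaptic arrivals
#'   falling beyond it have not yet reached their synapses and are ignored
#'   (matches a simulation stopped at `t_end`).
#' @return `synapses` with updated `weight`.
#' @export
apply_stdp <- function(spikes, synapses, params = sorn_params(),
                       t_end = Inf) {
  stdp <- params$stdp
  delay <- params$connectivity$delay_ee
  if (nrow(spikes) == 0 || nrow(synapses) == 0) return(synapses)
  n <- max(c(spikes$neuron_id, synapses$pre, synapses$post))
  last_arr <- rep(-Inf, n)   # last pre-arrival time per neuron
  last_post <- rep(-Inf, n)  # last spike time per neuron
  w <- synapses$weight
  in_syn <- split(seq_len(nrow(synapses)), synapses$post)
  out_syn <- split(seq_len(nrow(synapses)), synapses$pre)

  # event stream: spikes (as post events) and their delayed arrivals.
  # At equal times, post events are processed before arrivals: a post spike
  # pairs with the previous (potentially causal) arrival, while an arrival
  # pairs with the coincident post at dt = 0, which contributes nothing.
  arr_t <- spikes$time_ms + delay
  ev <- rbind(
    data.frame(t = spikes$time_ms, id = spikes$neuron_id, arrival = FALSE),
    data.frame(t = arr_t, id = spikes$neuron_id,
               arrival = TRUE)[arr_t <= t_end, ]
  )
  ev <- ev[order(ev$t, ev$arrival), ]
  eps <- 1e-6  # coincidence guard against float noise on the step grid
  for (i in seq_len(nrow(ev))) {
    tt <- ev$t[i]; id <- ev$id[i]
    if (ev$arrival[i]) {
      js <- out_syn[[as.character(id)]]
      for (j in js) {
        dt <- last_post[synapses$post[j]] - tt
        if (is.finite(dt) && dt < -eps) {
          w[j] <- max(0, w[j] + stdp$A_minus * exp(dt / stdp$tau_minus))
        }
      }
      last_arr[id] <- tt
    } else {
      js <- in_syn[[as.character(id)]]
      for (j in js) {
        dt <- tt - last_arr[synapses$pre[j]]
        if (is.finite(dt) && dt > eps) {
          w[j] <- max(0, w[j] + stdp$A_plus * exp(-dt / stdp$tau_plus))
        }
      }
      last_post[id] <- tt
    }
  }
  synapses$weight <- w
  synapses
}

#' Synaptic normalization
#'
#' Rescales each excitatory neuron's incoming E-to-E weights so that their
#' sum equals the neuron's target `w_total` (target connection fraction x
#' excitatory population size x mean synapse strength 0.8 x boundary
#' factor), preserving relative proportions. Neurons with no incoming
#' synapses are skipped. Applied once per simulated second by the engine.
#'
#' @param synapses tibble with `pre`, `post`, `weight` (E-to-E rows only).
#' @param w_total numeric vector of per-neuron targets, indexed by
#'   postsynaptic neuron id.
#' @return `synapses` with rescaled `weight`.
#' @examples
#' syn <- tibble::tibble(pre = c(1, 2), post = c(3, 3), weight = c(0.2, 0.6))
#' synaptic_normalization(syn, w_total = c(0, 0, 0.4))
#' @export
synaptic_normalization <- function(synapses, w_total) {
  if (nrow(synapses) == 0) return(synapses)
  synapses |>
    dplyr::group_by(.data$post) |>
    dplyr::mutate(weight = .data$weight *
                    w_total[.data$post[1]] / sum(.data$weight)) |>
    dplyr::ungroup()
}

#' Structural plasticity: growth
#'
#' Once per simulated second, a Gaussian number of candidate E-to-E
#' synapses (mean and SD `growth_mean`, `growth_sd`; rounded, clamped at 0)
#' is drawn from the distance kernel over *all* ordered excitatory pairs
#' (no self-pairs), each candidate selected with probability proportional
#' to [connection_probability()]. Candidates that already exist yield
#' nothing, so realized growth self-limits as each neuron's kernel
#' neighbourhood fills up — this saturation is what makes the recurrent
#' connection fraction settle at the kernel's effective volume fraction,
#' `2 * pi * sigma_c^2 / (width * height)` (0.1 at full scale), instead of
#' growing without bound. Accepted candidates are inserted at
#' `init_weight`. A synapse antiparallel to an existing one may be created;
#' only the exact ordered pair is blocked.
#'
#' @param synapses E-to-E synapse tibble (`pre`, `post`, `weight`).
#' @param neurons neuron table (only excitatory rows are used).
#' @param sp list with `growth_mean`, `growth_sd`, `init_weight`.
#' @param sigma_c kernel width, \eqn{\mu m}.
#' @param n_new optional fixed number of candidate draws (bypasses the
#'   Gaussian draw; used for testing).
#' @return the augmented synapse tibble.
#' @export
structural_growth <- function(synapses, neurons, sp = sorn_params()$sp,
                              sigma_c = 200, n_new = NULL) {
  e_ids <- neurons$id[neurons$is_exc]
  if (length(e_ids) < 2) return(synapses)
  if (is.null(n_new)) {
    n_new <- max(0L, as.integer(round(stats::rnorm(1, sp$growth_mean,
                                                   sp$growth_sd))))
  }
  if (n_new == 0) return(synapses)
  pairs <- expand.grid(pre = e_ids, post = e_ids)
  pairs <- pairs[pairs$pre != pairs$post, ]
  d <- sqrt((neurons$x[pairs$pre] - neurons$x[pairs$post])^2 +
            (neurons$y[pairs$pre] - neurons$y[pairs$post])^2)
  idx <- sample.int(nrow(pairs), min(n_new, nrow(pairs)), replace = FALSE,
                    prob = connection_probability(d, sigma_c))
  key <- paste(pairs$pre[idx], pairs$post[idx])
  existing <- paste(synapses$pre, synapses$post)
  keep <- !key %in% existing
  dplyr::bind_rows(synapses,
                   tibble::tibble(pre = pairs$pre[idx][keep],
                                  post = pairs$post[idx][keep],
                                  weight = sp$init_weight))
}

#' Structural plasticity: pruning
#'
#' Removes all E-to-E synapses whose weight is strictly below the pruning
#' threshold (1e-4 by default). Strict comparison means a weight exactly at
#' the threshold survives, and newborn synapses (1e-3) are always safely
#' above it.
#'
#' @param synapses E-to-E synapse tibble.
#' @param threshold pruning threshold.
#' @return the filtered tibble.
#' @export
structural_prune <- function(synapses,
                             threshold = sorn_params()$sp$prune_threshold) {
  synapses[synapses$weight >= threshold, , drop = FALSE]
}

#' Intrinsic plasticity threshold update
#'
#' Every timestep, each excitatory neuron's firing threshold moves by
#' `eta * (N_spikes - h)` where `N_spikes` is 1 if the neuron spiked in the
#' previous step and `h = r_target * dt` is the target number of spikes per
#' step (3e-4 at 3 Hz and dt = 0.1 ms). A neuron firing at exactly the
#' target rate has zero mean threshold drift.
#'
#' @param V_T threshold potential(s), mV.
#' @param spiked logical (or 0/1) spike indicator(s).
#' @param ip list with `eta` (mV) and `r_target` (Hz).
#' @param dt timestep, ms.
#' @return updated threshold(s).
#' @examples
#' ip_update(-48, TRUE)   # spike: threshold rises by ~0.1 mV
#' ip_update(-48, FALSE)  # silence: threshold creeps down by 3e-5 mV
#' @export
ip_update <- function(V_T, spiked, ip = sorn_params()$ip,
                      dt = sorn_params()$neuron$dt) {
  h <- ip$r_target * dt / 1000
  V_T + ip$eta * (as.numeric(spiked) - h)
}
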