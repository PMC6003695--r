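#' Advance a network by simulation
#'
#' Runs the clock-driven integration engine (0.1 ms forward-Euler steps,
#' C++) for `duration_ms`, with optional external stimulus blocks, and
#' returns the updated network together with tidy spike, trace and snapshot
#' tables. State (membrane, conductances, STP, STDP pairing memories,
#' thresholds, synapses, absolute time) carries over between calls, so a
#' long experiment can be run as one call or as consecutive phases.
#'
#' Once per simulated second (free-running from `t = 0`) the engine applies
#' structural growth, then pruning, then synaptic normalization, in that
#' order, so newborn synapses are normalized immediately.
#'
#' @param net a [sorn_network()].
#' @param duration_ms simulated time to advance, ms.
#' @param stimulus optional tibble of stimulus blocks ([stim_sweep()],
#'   [stim_cue()], [stim_bar()]), with *absolute* onset times.
#' @param seed integer seed for the engine's random streams (membrane noise,
#'   input Poisson processes, structural growth).
#' @param mechanisms named list of logical switches `stdp`, `stp`, `sn`,
#'   `sp`, `ip`, `noise`; unnamed mechanisms default to on. Switching a
#'   mechanism off removes it entirely (e.g. `noise = FALSE` gives the
#'   deterministic membrane equation).
#' @param snapshot_times times (absolute ms) at which to copy the full
#'   E-to-E weight table.
#' @param clusters optional [build_clusters()] result; if given, the
#'   per-second trace includes mean adjacent-cluster forward/backward
#'   weights.
#' @param record_spikes set `FALSE` to discard spikes (saves memory in long
#'   growth phases).
#' @param record_v neuron ids whose membrane potential is recorded at every
#'   step (for single-cell oracles and figures; keep short runs).
#' @return A list of class `sorn_sim` with elements
#'   \describe{
#'     \item{net}{the updated `sorn_network`,}
#'     \item{spikes}{tibble `time_ms`, `neuron_id`,}
#'     \item{trace}{per-second tibble `time_ms`, `cf`, `mean_weight`,
#'       `fwd_weight`, `bwd_weight`, `spikes_exc`, `spikes_inh`,
#'       `rate_exc`, `rate_inh` (population-mean rates in Hz),}
#'     \item{snapshots}{list of weight-table tibbles.}
#'   }
#' @examples
#' net <- sorn_network(n_exc = 30, n_inh = 6, seed = 1)
#' sim <- simulate_network(net, 2000, seed = 1)
#' sim$trace
#' @export
simulate_network <- function(net, duration_ms, stimulus = NULL, seed = 1,
                             mechanisms = list(), snapshot_times = numeric(0),
                             clusters = NULL, record_spikes = TRUE,
                             record_v = integer(0)) {
  stopifnot(inherits(net, "sorn_network"), duration_ms > 0)
  p <- net$params
  n_e <- sum(net$neurons$is_exc)
  n_i <- sum(!net$neurons$is_exc)

  mech_default <- list(stdp = TRUE, stp = TRUE, sn = TRUE, sp = TRUE,
                       ip = TRUE, noise = TRUE)
  bad <- setdiff(names(mechanisms), names(mech_default))
  if (length(bad)) stop("unknown mechanism switch: ", paste(bad, collapse = ", "))
  mech <- utils::modifyList(mech_default, mechanisms)

  nv <- p$neuron; cc <- p$connectivity
  par <- list(
    n_e = n_e, n_i = n_i, dt = nv$dt,
    E_L = nv$E_L, tau = nv$tau, E_e = nv$E_e, E_i = nv$E_i,
    tau_e = nv$tau_e, tau_i = nv$tau_i, sigma = nv$sigma_noise,
    V_reset_E = nv$V_reset_E, V_reset_I = nv$V_reset_I,
    refrac_steps = as.integer(round(nv$t_refrac / nv$dt)),
    eta_ip = p$ip$eta, h_ip = p$ip$r_target * nv$dt / 1000,
    U = p$stp$U, tau_f = p$stp$tau_f, tau_d = p$stp$tau_d,
    A_plus = p$stdp$A_plus, A_minus = p$stdp$A_minus,
    tau_plus = p$stdp$tau_plus, tau_minus = p$stdp$tau_minus,
    delay_ee_steps = as.integer(round(cc$delay_ee / nv$dt)),
    delay_ei_steps = as.integer(round(cc$delay_ei / nv$dt)),
    delay_ie_steps = as.integer(round(cc$delay_ie / nv$dt)),
    delay_ii_steps = as.integer(round(cc$delay_ii / nv$dt)),
    growth_mean = p$sp$growth_mean, growth_sd = p$sp$growth_sd,
    init_weight = p$sp$init_weight, prune_threshold = p$sp$prune_threshold,
    sigma_c = cc$sigma_c,
    n_input = p$stimulus$n_input, w_ff = p$stimulus$w_ff,
    w_total = net$w_total
  )

  syn <- net$synapses
  pick <- function(cls) {
    s <- syn[syn$class == cls, , drop = FALSE]
    list(pre = as.integer(s$pre), post = as.integer(s$post), weight = s$weight)
  }
  ee <- pick("EE")
  fixed <- list(EI = pick("EI"), IE = pick("IE"), II = pick("II"))

  if (is.null(stimulus) || nrow(stimulus) == 0) {
    stim_mat <- matrix(numeric(0), nrow = 0, ncol = 10)
  } else {
    stimulus <- stimulus[order(stimulus$t0), , drop = FALSE]
    stim_mat <- cbind(stimulus$t0, stimulus$t_end,
                      stimulus$x0, stimulus$y0, stimulus$x1, stimulus$y1,
                      stimulus$r_max, stimulus$alpha, stimulus$beta,
                      as.numeric(stimulus$type == "bar"))
  }

  cl_id <- integer(n_e)
  if (!is.null(clusters)) {
    cl_id <- cluster_id_vector(clusters, n_e)
  }

  st <- net$state
  st$time_ms <- net$time_ms
  if (is.null(st$last_arr)) st$last_arr <- rep(-1e18, n_e)
  if (is.null(st$last_post)) st$last_post <- rep(-1e18, n_e)
  st$refrac <- as.integer(st$refrac)

  res <- .sim_engine(st, net$neurons$x, net$neurons$y, ee, fixed, par, mech,
                     stim_mat, duration_ms, as.numeric(snapshot_times),
                     as.integer(cl_id), as.integer(seed), record_spikes,
                     as.integer(record_v))

  out_state <- res$state
  net$time_ms <- out_state$time_ms
  out_state$time_ms <- NULL
  net$state <- out_state
  ee_new <- tibble::tibble(pre = res$ee$pre, post = res$ee$post,
                           weight = res$ee$weight,
                           class = factor("EE", levels = levels(syn$class)),
                           delay = cc$delay_ee)
  net$synapses <- dplyr::bind_rows(ee_new, syn[syn$class != "EE", , drop = FALSE])

  trace <- tibble::as_tibble(res$trace)
  if (nrow(trace) > 0) {
    trace$rate_exc <- trace$spikes_exc / n_e
    trace$rate_inh <- if (n_i > 0) trace$spikes_inh / n_i else NA_real_
  }
  structure(
    list(net = net,
         spikes = tibble::tibble(time_ms = res$spike_t,
                                 neuron_id = res$spike_id),
         trace = trace,
         snapshots = lapply(res$snapshots, function(s) {
           tibble::tibble(time_ms = rep(s$time_ms, length(s$pre)),
                          pre = s$pre, post = s$post, weight = s$weight)
         }),
         voltage = if (length(record_v) > 0) {
           nt <- nrow(res$v_trace)
           tibble::tibble(
             time_ms = rep(net$time_ms - duration_ms + seq_len(nt) * p$neuron$dt,
                           length(record_v)),
             neuron_id = rep(as.integer(record_v), each = nt),
             V = as.vector(res$v_trace))
         } else NULL),
    class = "sorn_sim"
  )
}

#' @export
print.sorn_sim <- function(x, ...) {
  cat("<sorn_sim> ", nrow(x$spikes), " spikes, up to t = ",
      x$net$time_ms / 1000, " s\n", sep = "")
  invisible(x)
}
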