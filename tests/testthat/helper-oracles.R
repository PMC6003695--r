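# Independent brute-force oracles used to check the incremental
# implementations. These deliberately share no code with the package
# internals: per-synapse double loops over full spike lists.

# Nearest-neighbour STDP by chronological per-synapse replay: every post
# spike pairs with the most recent presynaptic arrival, every presynaptic
# arrival pairs with the most recent post spike; weight clipped at 0 after
# each event, in time order.
brute_stdp <- function(spikes, synapses, params = sorn_params(), t_end = Inf) {
  stdp <- params$stdp
  delay <- params$connectivity$delay_ee
  w_out <- synapses$weight
  for (j in seq_len(nrow(synapses))) {
    pre_arr <- sort(spikes$time_ms[spikes$neuron_id == synapses$pre[j]]) + delay
    pre_arr <- pre_arr[pre_arr <= t_end]
    posts <- sort(spikes$time_ms[spikes$neuron_id == synapses$post[j]])
    ev <- rbind(data.frame(t = pre_arr, kind = "arr"),
                data.frame(t = posts, kind = "post"))
    ev <- ev[order(ev$t, ev$kind == "arr"), ]  # posts first at ties
    w <- synapses$weight[j]
    eps <- 1e-6
    for (i in seq_len(nrow(ev))) {
      if (ev$kind[i] == "post") {
        # a post spike pairs with the latest strictly earlier arrival
        prev_arr <- pre_arr[pre_arr < ev$t[i] - eps]
        if (length(prev_arr)) {
          dt <- ev$t[i] - max(prev_arr)
          w <- max(0, w + stdp$A_plus * exp(-dt / stdp$tau_plus))
        }
      } else {
        # an arrival pairs with the latest post up to and including a
        # coincident one (dt = 0 contributes nothing but blocks older posts)
        prev_post <- posts[posts < ev$t[i] + eps]
        if (length(prev_post)) {
          dt <- max(prev_post) - ev$t[i]
          if (dt < -eps) {
            w <- max(0, w + stdp$A_minus * exp(dt / stdp$tau_minus))
          }
        }
      }
    }
    w_out[j] <- w
  }
  synapses$weight <- w_out
  synapses
}

# Poisson spike table on n neurons over (0, t_max_ms)
poisson_spikes <- function(n, rate_hz, t_max_ms, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    k <- rpois(1, rate_hz * t_max_ms / 1000)
    if (k == 0) return(NULL)
    tibble::tibble(time_ms = sort(runif(k, 0, t_max_ms)), neuron_id = i)
  })
  dplyr::bind_rows(out)
}

# 2D quadrature of the unit Gaussian over the grid rectangle (checks the
# separable closed form used for the boundary factor)
quad_boundary_factor <- function(x0, y0, width, height, sigma, n = 400) {
  gx <- seq(0, width, length.out = n)
  gy <- seq(0, height, length.out = n)
  fx <- dnorm(gx, x0, sigma)
  fy <- dnorm(gy, y0, sigma)
  wts <- function(g) { d <- diff(g); c(d[1]/2, (d[-1] + d[-length(d)])/2, d[length(d)]/2) }
  sum(fx * wts(gx)) * sum(fy * wts(gy))
}
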