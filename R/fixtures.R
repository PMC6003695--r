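#' Reduced test network
#'
#' Builds a scaled-down network that stays in the same structural regime as
#' the full model: the sheet is shrunk by `scale` in each linear dimension
#' (default `sqrt(n_exc / 1000)`, preserving neuron density) and the
#' structural-growth rate is rescaled by `(n_exc / 1000)^2` — the number of
#' possible excitatory pairs scales quadratically, so this preserves the
#' connection-fraction equilibrium. All other parameters keep their full
#' defaults.
#'
#' @param n_exc excitatory count (>= 10); inhibitory count is 0.2 of it.
#' @param scale linear geometry scale factor; `1` keeps the full-size sheet
#'   (useful when the stimulus geometry must stay unchanged).
#' @param params base parameters (before rescaling).
#' @param seed optional RNG seed.
#' @param ... further overrides applied to `params` first (as in
#'   [sorn_params()]).
#' @return a [sorn_network()].
#' @examples
#' net <- make_mini_network(n_exc = 50, seed = 1)
#' net$params$sp$growth_mean  # 6000 * (50/1000)^2 = 15
#' @export
make_mini_network <- function(n_exc = 100, scale = sqrt(n_exc / 1000),
                              params = sorn_params(), seed = NULL, ...) {
  if (n_exc < 10) stop("n_exc must be at least 10")
  if (scale <= 0) stop("inconsistent scale")
  params <- modify_params(unclass(params), list(...))
  f <- (n_exc / 1000)^2
  params$geometry$width <- params$geometry$width * scale
  params$geometry$height <- params$geometry$height * scale
  params$sp$growth_mean <- params$sp$growth_mean * f
  params$sp$growth_sd <- params$sp$growth_sd * f
  class(params) <- "sorn_params"
  sorn_network(n_exc = n_exc, n_inh = round(0.2 * n_exc), params = params,
               seed = seed)
}

#' Scripted sequence spikes
#'
#' Constructs a spike record with known ground truth for testing the
#' replay analysis: in each trial, every cluster emits a burst of spikes at
#' `onset + rank * separation_ms` (plus optional Gaussian jitter), where
#' `rank` is the cluster's position in `order` (the offset keeps the first
#' burst's rate peak inside the analysis window). With zero jitter and the
#' natural order, every trial has a Spearman score of exactly 1 and a
#' recall speed equal to the centre spacing divided by `separation_ms`.
#'
#' @param clusters a [build_clusters()] result.
#' @param order integer permutation of the cluster indices: the firing
#'   order (position in the vector = firing rank).
#' @param n_trials number of trials.
#' @param separation_ms time between consecutive cluster bursts, ms.
#' @param jitter_ms Gaussian SD added to each spike time, ms.
#' @param spikes_per_burst spikes per cluster burst (spread over its
#'   members cyclically).
#' @param period_ms trial period, ms.
#' @param phase phase label for the generated trials.
#' @param seed RNG seed.
#' @return tibble `time_ms`, `neuron_id`, `phase`, `trial`, `t_rel` — the
#'   same columns as [run_experiment()] spikes.
#' @export
scripted_sequence_spikes <- function(clusters, order = NULL, n_trials = 10,
                                     separation_ms = 60, jitter_ms = 0,
                                     spikes_per_burst = 20,
                                     period_ms = 2000, phase = "test1",
                                     seed = 1) {
  stopifnot(separation_ms > 0)
  set.seed(seed)
  n_clu <- attr(clusters, "n_clu")
  if (is.null(order)) order <- seq_len(n_clu)
  stopifnot(sort(order) == seq_len(n_clu))
  out <- purrr::map_dfr(seq_len(n_trials), function(tr) {
    onset <- (tr - 1) * period_ms
    purrr::map_dfr(seq_along(order), function(rank) {
      cl <- order[rank]
      ids <- clusters$neuron_id[clusters$cluster == cl]
      if (length(ids) == 0) return(NULL)
      t0 <- rank * separation_ms
      tt <- t0 + (if (jitter_ms > 0) stats::rnorm(spikes_per_burst, 0, jitter_ms) else
                    rep(0, spikes_per_burst))
      tt <- pmax(0, tt)
      tibble::tibble(time_ms = onset + tt,
                     neuron_id = rep_len(ids, spikes_per_burst),
                     phase = phase, trial = tr, t_rel = tt)
    })
  })
  out[order(out$time_ms), ]
}
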