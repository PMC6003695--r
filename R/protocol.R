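#' Recording clusters along the stimulus axis
#'
#' Defines the multi-electrode-style recording abstraction: `n_clu` circles
#' of radius `r_clu` whose centres lie equidistantly on the line from
#' `x_start` to `x_goal`, with the boundaries of the outermost circles
#' touching the endpoints. Cluster membership is the set of excitatory
#' neurons within `r_clu` of a centre (assigned to the nearest centre if
#' circles overlap; for the default geometry the circles are disjoint).
#' Clusters are labelled `A` (nearest `x_start`) to `H`.
#'
#' @param neurons neuron table of the network.
#' @param x_start,x_goal endpoints of the axis, 2-vectors in \eqn{\mu m}.
#' @param n_clu number of clusters (>= 2).
#' @param r_clu circle radius, \eqn{\mu m}.
#' @return An object of class `sorn_clusters`: a tibble with one row per
#'   member neuron (`cluster` index, `label`, `neuron_id`, `axis_pos` =
#'   distance of the cluster centre from `x_start` along the axis), with
#'   the centre table in attribute `centers`.
#' @examples
#' net <- sorn_network(n_exc = 200, n_inh = 40, seed = 1)
#' cl <- build_clusters(net$neurons)
#' attr(cl, "centers")
#' @export
build_clusters <- function(neurons,
                           x_start = sorn_params()$stimulus$x_start,
                           x_goal = sorn_params()$stimulus$x_goal,
                           n_clu = 8, r_clu = 100) {
  if (n_clu < 2) stop("n_clu must be at least 2")
  len <- sqrt(sum((x_goal - x_start)^2))
  axis <- (x_goal - x_start) / len
  step <- (len - 2 * r_clu) / (n_clu - 1)
  s_along <- r_clu + (seq_len(n_clu) - 1) * step
  centers <- tibble::tibble(
    cluster = seq_len(n_clu),
    label = LETTERS[seq_len(n_clu)],
    cx = x_start[1] + s_along * axis[1],
    cy = x_start[2] + s_along * axis[2],
    axis_pos = s_along
  )
  exc <- neurons[neurons$is_exc, ]
  d2 <- outer(exc$x, centers$cx, "-")^2 + outer(exc$y, centers$cy, "-")^2
  nearest <- max.col(-d2)
  dmin <- sqrt(d2[cbind(seq_len(nrow(exc)), nearest)])
  inside <- dmin <= r_clu
  member <- tibble::tibble(
    cluster = nearest[inside],
    label = centers$label[nearest[inside]],
    neuron_id = exc$id[inside],
    axis_pos = centers$axis_pos[nearest[inside]]
  )
  member <- member[order(member$cluster, member$neuron_id), ]
  structure(member, class = c("sorn_clusters", class(member)),
            centers = centers, n_clu = n_clu, r_clu = r_clu)
}

# per-excitatory-neuron cluster index (0 = unclustered), for the engine trace
cluster_id_vector <- function(clusters, n_e) {
  id <- integer(n_e)
  id[clusters$neuron_id] <- clusters$cluster
  id
}

#' Experiment protocol
#'
#' Builds the phase plan and stimulus schedule of the sequence-learning
#' experiment: a growth phase (no input; the network self-organizes), a
#' first test phase of cue trials, a relaxation pause, a training phase of
#' full moving-spot sweeps, another pause, and a second test phase. Cues
#' and sweeps recur once per `period_s`.
#'
#' Variants:
#' \describe{
#'   \item{`main`}{cue flashes at the sweep start point (default).}
#'   \item{`midcue` / `goalcue`}{cues at the mid / goal point (for
#'     `goalcue`, replay is scored along the reversed axis).}
#'   \item{`spont`}{no input at all during the test phases; spontaneous
#'     activity is analysed via cluster transition probabilities.}
#'   \item{`persist`}{as `main` with the second test phase tripled, for the
#'     persistence-of-training analysis.}
#'   \item{`shifted`}{training sweep displaced orthogonally to the cluster
#'     axis by 300 \eqn{\mu m} (clusters on y = 350, sweep on y = 650);
#'     cues stay on the cluster line.}
#'   \item{`bar`}{training by 100 ms bar flashes spanning start to goal.}
#'   \item{`flash`}{training by 100 ms spot flashes at the start point.}
#' }
#'
#' @param variant one of the experiment variants above.
#' @param params a [sorn_params()]; `v_spot` there sets the training sweep
#'   speed.
#' @param growth_s,test_s,train_s,relax_s,test2_s phase durations in
#'   seconds; `test2_s` defaults to `test_s` (or `3 * test_s` for
#'   `persist`). The full-scale experiment uses 400/100/200/10 s.
#' @param period_s trial period within test and training phases, s.
#' @return An object of class `sorn_protocol`: list with `phases` (tibble
#'   `phase`, `t_start`, `t_end` in ms), `blocks` (stimulus tibble with
#'   `phase` and `trial`), `onsets` (tibble of test/train trial onsets),
#'   `cluster_line` (2 x 2 matrix of the cluster axis endpoints),
#'   `reverse_axis` (logical; scoring direction), and `variant`.
#' @examples
#' pr <- sorn_protocol("main", growth_s = 10, test_s = 4, train_s = 6,
#'                     relax_s = 1)
#' pr$phases
#' @export
sorn_protocol <- function(variant = c("main", "midcue", "goalcue", "spont",
                                      "persist", "shifted", "bar", "flash"),
                          params = sorn_params(),
                          growth_s = 400, test_s = 100, train_s = 200,
                          relax_s = 10, test2_s = NULL, period_s = 2) {
  variant <- match.arg(variant)
  if (is.null(test2_s)) test2_s <- if (variant == "persist") 3 * test_s else test_s
  s <- params$stimulus

  if (variant == "shifted") {
    clu_start <- c(s$x_start[1], 350); clu_goal <- c(s$x_goal[1], 350)
    train_start <- c(s$x_start[1], 650); train_goal <- c(s$x_goal[1], 650)
  } else {
    clu_start <- s$x_start; clu_goal <- s$x_goal
    train_start <- s$x_start; train_goal <- s$x_goal
  }
  cue_at <- switch(variant,
    midcue = (clu_start + clu_goal) / 2,
    goalcue = clu_goal,
    clu_start)

  durs <- c(growth = growth_s, test1 = test_s, relax1 = relax_s,
            train = train_s, relax2 = relax_s, test2 = test2_s) * 1000
  t_start <- cumsum(c(0, durs[-length(durs)]))
  phases <- tibble::tibble(phase = names(durs), t_start = unname(t_start),
                           t_end = unname(t_start + durs))

  period <- period_s * 1000
  trial_onsets <- function(phase) {
    i <- match(phase, phases$phase)
    k <- floor((phases$t_end[i] - phases$t_start[i]) / period)
    tibble::tibble(phase = phase, trial = seq_len(k),
                   onset = phases$t_start[i] + (seq_len(k) - 1) * period)
  }
  ons <- dplyr::bind_rows(trial_onsets("test1"), trial_onsets("train"),
                          trial_onsets("test2"))

  mk_blocks <- function(phase) {
    o <- ons[ons$phase == phase, ]
    if (phase %in% c("test1", "test2")) {
      if (variant == "spont") return(NULL)
      b <- dplyr::bind_rows(lapply(o$onset, stim_cue, at = cue_at,
                                   params = params))
    } else {
      b <- switch(variant,
        bar = dplyr::bind_rows(lapply(o$onset, stim_bar, x_start = train_start,
                                      x_goal = train_goal, params = params)),
        flash = dplyr::bind_rows(lapply(o$onset, stim_cue, at = train_start,
                                        params = params)),
        dplyr::bind_rows(lapply(o$onset, stim_sweep, x_start = train_start,
                                x_goal = train_goal, params = params)))
    }
    b$phase <- phase
    b$trial <- o$trial
    b
  }
  blocks <- dplyr::bind_rows(mk_blocks("test1"), mk_blocks("train"),
                             mk_blocks("test2"))

  structure(list(phases = phases, blocks = blocks, onsets = ons,
                 cluster_line = rbind(start = clu_start, goal = clu_goal),
                 reverse_axis = (variant == "goalcue"),
                 variant = variant, period_ms = period),
            class = "sorn_protocol")
}

#' @export
print.sorn_protocol <- function(x, ...) {
  cat("<sorn_protocol> variant:", x$variant, "\n")
  print(x$phases)
  invisible(x)
}

#' Run a full sequence-learning experiment
#'
#' Executes a [sorn_protocol()] on one network instance in a single engine
#' run: growth, first test, training, second test, with cue/sweep stimulus
#' blocks at the protocol's trial onsets. Records all spikes with phase and
#' trial annotations, snapshots the E-to-E weights at every phase boundary,
#' and keeps the per-second connectivity/activity trace (including mean
#' adjacent-cluster forward and backward weights).
#'
#' The experiment is a pure function of (`net`, `protocol`, `seed`).
#'
#' @param net a freshly built [sorn_network()] (time 0).
#' @param protocol a [sorn_protocol()].
#' @param seed integer seed for all simulation randomness.
#' @param mechanisms mechanism switches passed to [simulate_network()]
#'   (e.g. `list(stdp = FALSE)` for a no-plasticity control).
#' @param extra_snapshots additional absolute times (ms) at which to
#'   snapshot the E-to-E weights, beyond the phase boundaries (used e.g.
#'   to follow the decay of training-induced weight changes through the
#'   final test phase).
#' @return An object of class `sorn_experiment`: list with `net` (final
#'   state), `spikes` (tibble `time_ms`, `neuron_id`, `phase`, `trial`,
#'   `t_rel` = time since trial onset), `trace`, `snapshots` (named by
#'   phase boundary), `clusters`, `protocol`.
#' @examples
#' \donttest{
#' net <- make_mini_network(n_exc = 100, seed = 1)
#' pr <- sorn_protocol("main", params = net$params, growth_s = 20,
#'                     test_s = 10, train_s = 10, relax_s = 2)
#' ex <- run_experiment(net, pr, seed = 1)
#' }
#' @export
run_experiment <- function(net, protocol, seed = 1, mechanisms = list(),
                           extra_snapshots = numeric(0)) {
  stopifnot(inherits(net, "sorn_network"), inherits(protocol, "sorn_protocol"))
  clusters <- build_clusters(net$neurons,
                             x_start = protocol$cluster_line["start", ],
                             x_goal = protocol$cluster_line["goal", ],
                             n_clu = net$params$clusters$n_clu,
                             r_clu = net$params$clusters$r_clu)
  ph <- protocol$phases
  snap_times <- sort(unique(c(ph$t_end, extra_snapshots)))
  sim <- simulate_network(net, duration_ms = max(ph$t_end),
                          stimulus = protocol$blocks, seed = seed,
                          mechanisms = mechanisms,
                          snapshot_times = snap_times,
                          clusters = clusters)

  spikes <- sim$spikes
  # phases are right-open [t_start, t_end): a spike logged exactly at a
  # boundary belongs to the next phase, matching the trial arithmetic
  idx <- findInterval(spikes$time_ms, ph$t_start)
  idx[idx < 1] <- 1
  spikes$phase <- ph$phase[pmin(idx, nrow(ph))]
  spikes$trial <- NA_integer_
  spikes$t_rel <- NA_real_
  for (phname in unique(protocol$onsets$phase)) {
    sel <- spikes$phase == phname
    if (!any(sel)) next
    p0 <- ph$t_start[ph$phase == phname]
    tr <- floor((spikes$time_ms[sel] - p0) / protocol$period_ms)
    spikes$trial[sel] <- as.integer(tr) + 1L
    spikes$t_rel[sel] <- spikes$time_ms[sel] - (p0 + tr * protocol$period_ms)
  }
  snaps <- sim$snapshots
  snap_t <- vapply(snaps, function(s) s$time_ms[1] %||% NA_real_, numeric(1))
  nm <- ph$phase[match(snap_t, ph$t_end)]
  nm[is.na(nm)] <- paste0("t", snap_t[is.na(nm)] / 1000)
  names(snaps) <- nm
  structure(list(net = sim$net, spikes = spikes, trace = sim$trace,
                 snapshots = snaps, clusters = clusters,
                 protocol = protocol),
            class = "sorn_experiment")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.sorn_experiment <- function(x, ...) {
  cat("<sorn_experiment> variant:", x$protocol$variant, "|",
      nrow(x$spikes), "spikes |", nrow(x$clusters), "clustered neurons\n")
  invisible(x)
}
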