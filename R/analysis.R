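#' Pairwise spike-count correlations
#'
#' Pearson correlation of binned spike counts for all disjoint neuron
#' pairs; the standard synchrony measure. Counts are taken in successive
#' bins of `bin_ms` over `window`; pairs involving a neuron with zero count
#' variance are excluded.
#'
#' @param spikes tibble with `time_ms`, `neuron_id`.
#' @param neuron_ids neurons to include (e.g. the excitatory ids).
#' @param bin_ms bin duration, ms (20 ms by default).
#' @param window length-2 numeric, analysis window in ms.
#' @return numeric vector of pairwise coefficients (one per included pair).
#' @export
pairwise_correlation <- function(spikes, neuron_ids, bin_ms = 20, window) {
  if (diff(window) <= bin_ms) stop("degenerate window")
  breaks <- seq(window[1], window[2], by = bin_ms)
  sel <- spikes$neuron_id %in% neuron_ids &
    spikes$time_ms >= window[1] & spikes$time_ms < breaks[length(breaks)]
  s <- spikes[sel, ]
  nb <- length(breaks) - 1
  bins <- findInterval(s$time_ms, breaks)
  ids <- match(s$neuron_id, neuron_ids)
  counts <- matrix(tabulate((ids - 1L) * nb + bins, nb * length(neuron_ids)),
                   nrow = nb, ncol = length(neuron_ids))
  v <- apply(counts, 2, stats::var)
  keep <- v > 0
  if (sum(keep) < 2) return(numeric(0))
  cm <- stats::cor(counts[, keep, drop = FALSE])
  cm[upper.tri(cm)]
}

#' Interspike-interval statistics
#'
#' Per-neuron interspike intervals, their coefficient of variation
#' (CV = sd/mean; 1 for a Poisson process, 0 for a clock), and a pooled
#' exponential fit restricted to intervals above `fit_min_ms` (where the
#' refractory distortion is negligible): the maximum-likelihood rate of the
#' shifted exponential, `1 / (mean(isi - fit_min_ms))` over qualifying
#' intervals.
#'
#' @param spikes tibble with `time_ms`, `neuron_id`.
#' @param fit_min_ms lower cutoff for the exponential fit, ms.
#' @return list with `per_neuron` (tibble `neuron_id`, `n_spikes`,
#'   `mean_isi`, `cv`; neurons with < 2 spikes are skipped), `isi`
#'   (pooled intervals, ms) and `exp_rate` (1/ms, NA if too few intervals).
#' @export
isi_stats <- function(spikes, fit_min_ms = 50) {
  per <- spikes |>
    dplyr::arrange(.data$neuron_id, .data$time_ms) |>
    dplyr::group_by(neuron_id = .data$neuron_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(isi = list(diff(.data$time_ms)), .groups = "drop") |>
    dplyr::mutate(n_spikes = lengths(.data$isi) + 1L,
                  mean_isi = vapply(.data$isi, mean, numeric(1)),
                  cv = vapply(.data$isi, function(v) {
                    stats::sd(v) / mean(v)
                  }, numeric(1)))
  pooled <- unlist(per$isi)
  tail_isi <- pooled[pooled > fit_min_ms]
  list(per_neuron = per[c("neuron_id", "n_spikes", "mean_isi", "cv")],
       isi = pooled,
       exp_rate = if (length(tail_isi) >= 10) {
         1 / mean(tail_isi - fit_min_ms)
       } else NA_real_)
}

# Gaussian-kernel rate estimate on a 1 ms grid (FFT-free running
# convolution). `times` in ms within [t0, t1); returns Hz. The kernel has
# unit mass so sum(rate) * 1ms / 1000 equals the spike count.
kernel_rate <- function(times, t0, t1, tau_rate = 50, grid_ms = 1) {
  grid <- seq(t0 + grid_ms / 2, t1, by = grid_ms)
  counts <- tabulate(findInterval(times, seq(t0, t1, by = grid_ms),
                                  rightmost.closed = TRUE),
                     nbins = length(grid))
  half <- ceiling(4 * tau_rate / grid_ms)
  kern <- stats::dnorm(seq(-half, half) * grid_ms, sd = tau_rate) * grid_ms
  kern <- kern / sum(kern)
  padded <- c(rep(0, half), counts, rep(0, half))
  sm <- stats::filter(padded, kern, sides = 2)
  rate <- as.numeric(sm[(half + 1):(half + length(grid))])
  tibble::tibble(time_ms = grid, rate = rate * 1000 / grid_ms)
}

#' Cluster firing-rate curves
#'
#' Pools each cluster's spikes and convolves them with a unit-mass Gaussian
#' kernel of width `tau_rate` (50 ms), sampled on a 1 ms grid, giving the
#' cluster rate in Hz.
#'
#' @param spikes spike tibble (`time_ms`, `neuron_id`).
#' @param clusters a [build_clusters()] result.
#' @param window length-2 window in ms.
#' @param tau_rate Gaussian kernel width, ms.
#' @param grid_ms sampling resolution of the rate curve, ms.
#' @return tibble `cluster`, `label`, `time_ms`, `rate`.
#' @export
cluster_rates <- function(spikes, clusters, window, tau_rate = 50,
                          grid_ms = 1) {
  centers <- attr(clusters, "centers")
  purrr::map_dfr(centers$cluster, function(cl) {
    ids <- clusters$neuron_id[clusters$cluster == cl]
    tt <- spikes$time_ms[spikes$neuron_id %in% ids &
                           spikes$time_ms >= window[1] &
                           spikes$time_ms <= window[2]]
    rc <- kernel_rate(tt, window[1], window[2], tau_rate, grid_ms)
    rc$cluster <- cl
    rc$label <- centers$label[cl]
    rc
  })
}

# midpoints of strict local maxima of a sampled curve; plateau runs
# bounded by lower values on both sides collapse to their midpoint index.
local_maxima_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (j in seq_len(k)) {
    left_lower <- j > 1 && r$values[j - 1] < r$values[j]
    right_lower <- j < k && r$values[j + 1] < r$values[j]
    if (left_lower && right_lower) {
      out <- c(out, floor((starts[j] + ends[j]) / 2))
    }
  }
  out
}

#' Cluster firing time
#'
#' The firing time of a cluster in a trial is the time of the first local
#' maximum of its rate curve within the analysis window (0-500 ms after cue
#' onset). Plateaus resolve to their midpoint; a curve with no interior
#' maximum (monotone or empty) yields `NA`.
#'
#' @param rate_curve tibble `time_ms`, `rate` (one cluster).
#' @param window length-2 window, ms.
#' @return time of the first rate peak (ms) or `NA`.
#' @export
firing_time <- function(rate_curve, window = range(rate_curve$time_ms)) {
  sel <- rate_curve$time_ms >= window[1] & rate_curve$time_ms <= window[2]
  rr <- rate_curve$rate[sel]
  tt <- rate_curve$time_ms[sel]
  idx <- local_maxima_idx(rr)
  if (length(idx) == 0) return(NA_real_)
  tt[idx[1]]
}

#' Per-trial cluster firing times
#'
#' For every test trial, computes each cluster's rate curve within
#' `window_ms` after the trial onset and extracts its firing time.
#'
#' @param experiment a [run_experiment()] result, or a spike tibble with
#'   `phase`, `trial`, `t_rel` columns plus a `clusters` argument.
#' @param phase which phase to analyse (`"test1"` or `"test2"`).
#' @param clusters required if `experiment` is a plain spike table.
#' @param window_ms analysis window after each trial onset, ms.
#' @param tau_rate rate kernel width, ms.
#' @return tibble `phase`, `trial`, `cluster`, `label`, `axis_pos`,
#'   `t_fire` (ms after onset; `NA` when the cluster has no rate peak).
#' @export
replay_times <- function(experiment, phase = "test1", clusters = NULL,
                         window_ms = 500, tau_rate = 50) {
  if (inherits(experiment, "sorn_experiment")) {
    spikes <- experiment$spikes
    clusters <- experiment$clusters
  } else {
    spikes <- experiment
    if (is.null(clusters)) stop("clusters required with a plain spike table")
  }
  sp <- spikes[spikes$phase == phase & !is.na(spikes$trial) &
                 spikes$t_rel >= 0 & spikes$t_rel <= window_ms, ]
  centers <- attr(clusters, "centers")
  trials <- sort(unique(sp$trial))
  purrr::map_dfr(trials, function(tr) {
    sp_tr <- sp[sp$trial == tr, ]
    purrr::map_dfr(centers$cluster, function(cl) {
      ids <- clusters$neuron_id[clusters$cluster == cl]
      tt <- sp_tr$t_rel[sp_tr$neuron_id %in% ids]
      rc <- kernel_rate(tt, 0, window_ms, tau_rate)
      tibble::tibble(phase = phase, trial = tr, cluster = cl,
                     label = centers$label[cl],
                     axis_pos = centers$axis_pos[cl],
                     t_fire = firing_time(rc))
    })
  })
}

#' Spearman replay score
#'
#' Rank correlation (average-rank ties) between cluster firing times and
#' cluster positions along the stimulus axis. A coefficient of +1 means the
#' clusters fired in exact training order. Clusters without a firing time
#' are dropped from the trial; the score is `NA` when fewer than 2 clusters
#' fired.
#'
#' @param t_fire firing times, ms.
#' @param axis_pos cluster positions along the scoring axis, \eqn{\mu m}.
#' @return Spearman's rho in \[-1, 1\], or `NA`.
#' @examples
#' spearman_replay(c(10, 20, 30, 40), c(1, 2, 4, 3))  # 0.8
#' @export
spearman_replay <- function(t_fire, axis_pos) {
  ok <- !is.na(t_fire) & !is.na(axis_pos)
  if (sum(ok) < 2) return(NA_real_)
  suppressWarnings(stats::cor(t_fire[ok], axis_pos[ok], method = "spearman"))
}

#' Per-trial replay scores
#'
#' Applies [spearman_replay()] to each trial of a [replay_times()] table.
#' For goal-point cues the scoring axis is reversed (`reverse = TRUE`), so
#' positive scores again mean replay in the cued direction.
#'
#' @param times a [replay_times()] table.
#' @param reverse score along the reversed (goal-to-start) axis.
#' @return tibble `phase`, `trial`, `rho`, `n_clusters` (clusters with a
#'   firing time). Trials with `n_clusters < 2` have `rho = NA` and are
#'   excluded from distribution comparisons downstream.
#' @export
replay_scores <- function(times, reverse = FALSE) {
  sgn <- if (reverse) -1 else 1
  times |>
    dplyr::group_by(phase = .data$phase, trial = .data$trial) |>
    dplyr::summarise(
      rho = spearman_replay(.data$t_fire, sgn * .data$axis_pos),
      n_clusters = sum(!is.na(.data$t_fire)), .groups = "drop")
}

#' Replay-distribution shift test
#'
#' Compares the trial-wise Spearman score distributions before and after
#' training: difference of means and a two-sample Kolmogorov-Smirnov test
#' (scores pooled over trials, and over network instances when several are
#' supplied).
#'
#' @param rho_before,rho_after numeric score samples (`NA`s dropped).
#' @return object of class `sorn_shift`: list with `mean_before`,
#'   `mean_after`, `delta_mean`, `ks_statistic`, `p_value`, `n_before`,
#'   `n_after`. Has [generics::tidy()] and [generics::glance()] methods.
#' @export
shift_test <- function(rho_before, rho_after) {
  b <- rho_before[!is.na(rho_before)]
  a <- rho_after[!is.na(rho_after)]
  if (length(b) == 0 || length(a) == 0) stop("empty score sample")
  kt <- suppressWarnings(stats::ks.test(a, b))
  structure(list(mean_before = mean(b), mean_after = mean(a),
                 delta_mean = mean(a) - mean(b),
                 ks_statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_before = length(b), n_after = length(a)),
            class = "sorn_shift")
}

#' @export
print.sorn_shift <- function(x, ...) {
  cat(sprintf(
    "<sorn_shift> mean rho %.3f -> %.3f (delta %+.3f), KS D = %.3f, P = %.2g\n",
    x$mean_before, x$mean_after, x$delta_mean, x$ks_statistic, x$p_value))
  invisible(x)
}

#' Cluster-pair cross-correlograms
#'
#' For each trial and each cluster pair, cross-correlates the pooled,
#' binned cluster spike trains within the post-onset window; correlograms
#' are then pooled by the difference in cluster position (1 to
#' `n_clu - 1`), with positive lags meaning the cluster further along the
#' axis fires later. The before/after correlograms and their difference are
#' each min-max normalized to \[0, 1\] independently per distance group.
#'
#' @param experiment a [run_experiment()] result.
#' @param phases the two phases to compare.
#' @param bin_ms correlogram bin, ms.
#' @param max_lag_ms maximum lag, ms.
#' @param window_ms post-onset analysis window, ms.
#' @return tibble `distance`, `lag_ms`, `before`, `after`, `difference`
#'   (each normalized to \[0, 1\] within its distance group).
#' @export
cluster_cross_correlogram <- function(experiment,
                                      phases = c("test1", "test2"),
                                      bin_ms = 10, max_lag_ms = 250,
                                      window_ms = 500) {
  clusters <- experiment$clusters
  n_clu <- attr(clusters, "n_clu")
  lags <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  n_lag_side <- max_lag_ms / bin_ms
  breaks <- seq(0, window_ms, by = bin_ms)
  nb <- length(breaks) - 1

  one_phase <- function(phname) {
    sp <- experiment$spikes
    sp <- sp[sp$phase == phname & !is.na(sp$trial) &
               sp$t_rel >= 0 & sp$t_rel < window_ms, ]
    acc <- matrix(0, nrow = n_clu - 1, ncol = length(lags))
    for (tr in unique(sp$trial)) {
      sp_tr <- sp[sp$trial == tr, ]
      counts <- sapply(seq_len(n_clu), function(cl) {
        ids <- clusters$neuron_id[clusters$cluster == cl]
        tabulate(findInterval(sp_tr$t_rel[sp_tr$neuron_id %in% ids],
                              breaks, rightmost.closed = TRUE), nbins = nb)
      })
      for (i in seq_len(n_clu - 1)) {
        for (j in (i + 1):n_clu) {
          cc <- crosscount(counts[, i], counts[, j], n_lag_side)
          acc[j - i, ] <- acc[j - i, ] + cc
        }
      }
    }
    acc
  }
  before <- one_phase(phases[1])
  after <- one_phase(phases[2])
  diffm <- after - before
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  }
  purrr::map_dfr(seq_len(n_clu - 1), function(d) {
    tibble::tibble(distance = d, lag_ms = lags,
                   before = norm01(before[d, ]),
                   after = norm01(after[d, ]),
                   difference = norm01(diffm[d, ]))
  })
}

# raw cross-correlation of two count vectors: sum_t a(t) * b(t + lag)
# for lags -n_side..n_side (in bins)
crosscount <- function(a, b, n_side) {
  nb <- length(a)
  vapply(-n_side:n_side, function(l) {
    if (l >= 0) {
      idx <- seq_len(nb - l)
      sum(a[idx] * b[idx + l])
    } else {
      idx <- seq_len(nb + l)
      sum(a[idx - l] * b[idx])
    }
  }, numeric(1))
}

#' Spontaneous-activity transition probabilities
#'
#' From input-free test-phase activity: computes each cluster's rate curve
#' over the whole phase, finds all local rate maxima, merges them into one
#' time-ordered sequence of cluster labels, and estimates first-order
#' transition probabilities `P(next = j | current = i)` by counting.
#' Rows of clusters that never fire are `NA`.
#'
#' @param spikes spike tibble (use the full phase).
#' @param clusters a [build_clusters()] result.
#' @param window length-2 phase window, ms.
#' @param tau_rate rate kernel width, ms.
#' @return list with `matrix` (n_clu x n_clu transition probabilities,
#'   rows = source) and `sequence` (tibble `time_ms`, `cluster`).
#' @export
transition_probabilities <- function(spikes, clusters, window,
                                     tau_rate = 50) {
  n_clu <- attr(clusters, "n_clu")
  rates <- cluster_rates(spikes, clusters, window, tau_rate)
  peaks <- purrr::map_dfr(seq_len(n_clu), function(cl) {
    rc <- rates[rates$cluster == cl, ]
    idx <- local_maxima_idx(rc$rate)
    tibble::tibble(time_ms = rc$time_ms[idx], cluster = cl)
  })
  peaks <- peaks[order(peaks$time_ms, peaks$cluster), ]
  mat <- matrix(NA_real_, n_clu, n_clu,
                dimnames = list(LETTERS[1:n_clu], LETTERS[1:n_clu]))
  if (nrow(peaks) >= 2) {
    from <- peaks$cluster[-nrow(peaks)]
    to <- peaks$cluster[-1]
    for (i in seq_len(n_clu)) {
      n_from <- sum(from == i)
      if (n_from > 0) {
        mat[i, ] <- tabulate(to[from == i], nbins = n_clu) / n_from
      }
    }
  }
  list(matrix = mat, sequence = peaks)
}

#' Mean change in directed transition probabilities
#'
#' Summarizes a before/after pair of transition matrices as the mean change
#' of forward transitions (towards the goal, spanning at most `max_span`
#' clusters) and of the corresponding backward transitions.
#'
#' @param before,after transition matrices from
#'   [transition_probabilities()].
#' @param max_span maximum cluster span of the included transitions (2 =
#'   adjacent or separated by one cluster).
#' @return tibble with `direction` (forward/backward) and `mean_change`.
#' @export
transition_change <- function(before, after, max_span = 2) {
  n <- nrow(before)
  d <- after - before
  fwd <- bwd <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && j - i <= max_span) fwd <- c(fwd, d[i, j])
      if (i > j && i - j <= max_span) bwd <- c(bwd, d[i, j])
    }
  }
  tibble::tibble(direction = c("forward", "backward"),
                 mean_change = c(mean(fwd, na.rm = TRUE),
                                 mean(bwd, na.rm = TRUE)))
}

#' Recall speed
#'
#' For trials whose replay score exceeds `min_rho` (0.9), regresses cluster
#' centre position along the axis on cluster firing time (ordinary least
#' squares); the slope is the trial's recall speed in \eqn{\mu m}/ms.
#'
#' @param times a [replay_times()] table.
#' @param scores the matching [replay_scores()] table.
#' @param min_rho inclusion threshold on the Spearman score (strict `>`).
#' @return tibble `trial`, `rho`, `speed` (one row per qualifying trial);
#'   zero rows when no trial qualifies.
#' @export
recall_speed <- function(times, scores, min_rho = 0.9) {
  empty <- tibble::tibble(trial = integer(0), rho = numeric(0),
                          speed = numeric(0))
  ok <- scores$trial[!is.na(scores$rho) & scores$rho > min_rho]
  if (length(ok) == 0) return(empty)
  out <- purrr::map_dfr(ok, function(tr) {
    tf <- times[times$trial == tr & !is.na(times$t_fire), ]
    if (nrow(tf) < 2 || stats::var(tf$t_fire) == 0) return(NULL)
    fit <- stats::lm(axis_pos ~ t_fire, data = tf)
    tibble::tibble(trial = tr,
                   rho = scores$rho[scores$trial == tr][1],
                   speed = unname(stats::coef(fit)[2]))
  })
  if (nrow(out) == 0) empty else out
}

#' Persistence of the training effect
#'
#' A *match* is a test trial with replay score above `threshold` (0.6). The
#' post-training test phase is cut into bins of `bin_s` seconds and the
#' percentage of matches in each bin is compared with the overall
#' pre-training percentage.
#'
#' @param scores_before,scores_after [replay_scores()] tables for the two
#'   test phases; `scores_after` must carry trial onsets (column `onset`,
#'   ms relative to the phase start; if absent, trials are assumed
#'   `period_ms` apart).
#' @param threshold match threshold on rho (strict `>`).
#' @param bin_s bin duration, seconds.
#' @param period_ms trial period used to place trials in time when no
#'   `onset` column is present.
#' @return tibble `bin`, `t_mid_s` (bin midpoint, s after training),
#'   `pct_after`, `pct_before`, `change` (percentage points).
#' @export
match_persistence <- function(scores_before, scores_after, threshold = 0.6,
                              bin_s = 60, period_ms = 2000) {
  pb <- 100 * mean(scores_before$rho > threshold, na.rm = TRUE)
  sa <- scores_after[!is.na(scores_after$rho), ]
  onset <- if ("onset" %in% names(sa)) sa$onset else (sa$trial - 1) * period_ms
  bin <- floor(onset / (bin_s * 1000)) + 1
  out <- tibble::tibble(bin = bin, match = sa$rho > threshold) |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(pct_after = 100 * mean(.data$match), .groups = "drop")
  out$t_mid_s <- (out$bin - 0.5) * bin_s
  out$pct_before <- pb
  out$change <- out$pct_after - pb
  out[c("bin", "t_mid_s", "pct_after", "pct_before", "change")]
}

#' Convert a synaptic weight to a postsynaptic-potential amplitude
#'
#' Peak membrane deflection caused by a single presynaptic spike of the
#' given weight on a postsynaptic neuron at rest, from the closed-form
#' solution of the membrane equation linearized at the resting potential
#' (difference of exponentials with the membrane and synaptic time
#' constants):
#' \deqn{\Delta V_{peak} = w (E_{rev} - E_L)
#'   \frac{\tau_s}{\tau - \tau_s}\left[(\tau/\tau_s)^{-\tau_s/(\tau-\tau_s)}
#'   - (\tau/\tau_s)^{-\tau/(\tau-\tau_s)}\right]}
#' Excitatory inputs (classes `EE`, `EI`) use the excitatory reversal
#' potential and synaptic time constant; inhibitory inputs (`IE`, `II`) the
#' inhibitory ones, giving a negative deflection.
#'
#' @param weight synaptic weight(s), dimensionless.
#' @param class connection class (`EE`, `EI`, `IE`, `II`).
#' @param params a [sorn_params()] (membrane constants).
#' @return peak deflection(s), mV (signed).
#' @examples
#' weight_to_psp(0.8, "EE")
#' @export
weight_to_psp <- function(weight, class = c("EE", "EI", "IE", "II"),
                          params = sorn_params()) {
  class <- match.arg(class)
  nv <- params$neuron
  exc <- class %in% c("EE", "EI")
  tau_s <- if (exc) nv$tau_e else nv$tau_i
  E_rev <- if (exc) nv$E_e else nv$E_i
  weight * (E_rev - nv$E_L) * psp_kernel_peak(nv$tau, tau_s)
}

# peak of the normalized difference-of-exponentials PSP kernel
# (limit t * exp(-t/tau) / tau for tau_s -> tau)
psp_kernel_peak <- function(tau, tau_s) {
  if (abs(tau - tau_s) < 1e-9) return(exp(-1))
  r <- tau / tau_s
  (tau_s / (tau - tau_s)) * (r^(-tau_s / (tau - tau_s)) - r^(-tau / (tau - tau_s)))
}

#' Population PSP summary
#'
#' Mean postsynaptic-potential amplitudes implied by the current weights,
#' by connection class. For E-to-E synapses the transmitted weight is the
#' stored weight times the short-term-plasticity factor `u * x`; the
#' summary evaluates that factor at its periodic steady state for a
#' presynaptic neuron firing at the intrinsic-plasticity target rate, which
#' is the operating point of the equilibrated network.
#'
#' @param net a `sorn_network`.
#' @return tibble `class`, `n_synapses`, `mean_weight`, `mean_psp_mV`
#'   (absolute amplitude).
#' @export
psp_summary <- function(net) {
  p <- net$params
  ux <- stp_steady_state(p$stp, p$ip$r_target)$eff
  purrr::map_dfr(c("EE", "EI", "IE", "II"), function(cl) {
    w <- net$synapses$weight[net$synapses$class == cl]
    if (length(w) == 0) {
      return(tibble::tibble(class = cl, n_synapses = 0L,
                            mean_weight = NA_real_, mean_psp_mV = NA_real_))
    }
    eff <- if (cl == "EE") w * ux else w
    tibble::tibble(class = cl, n_synapses = length(w),
                   mean_weight = mean(w),
                   mean_psp_mV = mean(abs(weight_to_psp(eff, cl, p))))
  })
}

#' Steady-state short-term plasticity factor
#'
#' Fixed point of the facilitation/depression dynamics for a presynaptic
#' neuron firing periodically at `rate` Hz: the pre-jump values `u*`, `x*`
#' and the transmitted factor `eff = u* x*`.
#'
#' @param stp list with `U`, `tau_f`, `tau_d`.
#' @param rate presynaptic firing rate, Hz.
#' @return list `u`, `x`, `eff`.
#' @export
stp_steady_state <- function(stp = sorn_params()$stp, rate = 3) {
  T_ms <- 1000 / rate
  fu <- exp(-T_ms / stp$tau_f)
  fx <- exp(-T_ms / stp$tau_d)
  # pre-jump fixed points of the jump + relaxation map
  u <- (stp$U * (1 - fu) + stp$U * fu) / (1 - fu * (1 - stp$U))
  x <- (1 - fx) / (1 - fx * (1 - u))
  list(u = u, x = x, eff = u * x)
}

#' Training-induced directional weight change
#'
#' Compares the E-to-E weights just before training with those just after
#' (phase-boundary snapshots `relax1` and `train` of a
#' [run_experiment()] result), paired over the synapses present at both
#' times, and summarizes the mean weight change of adjacent-cluster
#' synapses in the forward (towards the goal) and backward direction.
#' Training with a moving stimulus strengthens forward and weakens
#' backward connections (stripe-like connectivity); pairing over common
#' synapses removes the turnover noise that dominates raw per-pair means
#' in small networks.
#'
#' @param experiment a [run_experiment()] result with phase snapshots.
#' @param before,after names of the snapshots to compare.
#' @return tibble `direction` (forward/backward), `mean_dw`, `n_synapses`.
#' @export
training_weight_change <- function(experiment, before = "relax1",
                                   after = "train") {
  sb <- experiment$snapshots[[before]]
  sa <- experiment$snapshots[[after]]
  if (is.null(sb) || is.null(sa)) stop("missing phase snapshots")
  cl <- experiment$clusters
  n_e <- sum(experiment$net$neurons$is_exc)
  cid <- integer(n_e)
  cid[cl$neuron_id] <- cl$cluster
  kb <- paste(sb$pre, sb$post)
  ka <- paste(sa$pre, sa$post)
  common <- intersect(kb, ka)
  ia <- match(common, ka)
  dw <- sa$weight[ia] - sb$weight[match(common, kb)]
  c1 <- cid[sa$pre[ia]]
  c2 <- cid[sa$post[ia]]
  both <- c1 > 0 & c2 > 0
  fwd <- both & c2 == c1 + 1
  bwd <- both & c2 == c1 - 1
  tibble::tibble(direction = c("forward", "backward"),
                 mean_dw = c(mean(dw[fwd]), mean(dw[bwd])),
                 n_synapses = c(sum(fwd), sum(bwd)))
}

#' Mean adjacent-cluster weights
#'
#' Mean E-to-E weight from each cluster to its forward neighbour (towards
#' the goal) and to its backward neighbour, averaged over the adjacent
#' cluster pairs (pairs without any existing synapse contribute nothing).
#'
#' @param synapses synapse tibble (`pre`, `post`, `weight`; EE rows, or a
#'   snapshot table).
#' @param clusters a [build_clusters()] result.
#' @return tibble `direction` (forward/backward), `mean_weight`.
#' @export
adjacent_cluster_weights <- function(synapses, clusters) {
  n_e_max <- max(c(synapses$pre, synapses$post, clusters$neuron_id))
  cl <- integer(n_e_max)
  cl[clusters$neuron_id] <- clusters$cluster
  c1 <- cl[synapses$pre]
  c2 <- cl[synapses$post]
  both <- c1 > 0 & c2 > 0
  pair_mean <- function(sel, key) {
    if (!any(sel)) return(NA_real_)
    mean(tapply(synapses$weight[sel], key[sel], mean))
  }
  fwd <- c2 == c1 + 1 & both
  bwd <- c2 == c1 - 1 & both
  tibble::tibble(
    direction = c("forward", "backward"),
    mean_weight = c(pair_mean(fwd, c1), pair_mean(bwd, c2)))
}
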