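# The analysis layer is exercised against constructed spike data with
# known ground truth (scripted bursts, Poisson trains, closed forms).

make_cl <- function(seed = 7, n_exc = 400) {
  net <- sorn_network(n_exc = n_exc, n_inh = round(0.2 * n_exc), seed = seed)
  build_clusters(net$neurons)
}

test_that("pairwise correlations: identical trains 1, independent trains ~0", {
  sp_same <- tibble::tibble(time_ms = rep(seq(10, 4990, 35), 2),
                            neuron_id = rep(1:2, each = length(seq(10, 4990, 35))))
  cc <- pairwise_correlation(sp_same, 1:2, bin_ms = 20, window = c(0, 5000))
  expect_equal(unname(cc), 1)

  sp_pois <- poisson_spikes(30, rate_hz = 5, t_max_ms = 100000, seed = 3)
  cc2 <- pairwise_correlation(sp_pois, 1:30, bin_ms = 20, window = c(0, 1e5))
  expect_equal(length(cc2), choose(30, 2))
  se <- sd(cc2) / sqrt(length(cc2))
  expect_lt(abs(mean(cc2)), 4 * se + 1e-3)

  # wider bins widen the distribution but keep the mean near zero
  cc3 <- pairwise_correlation(sp_pois, 1:30, bin_ms = 80, window = c(0, 1e5))
  expect_gt(sd(cc3), sd(cc2))
  expect_lt(abs(mean(cc3)), 0.02)

  expect_error(pairwise_correlation(sp_same, 1:2, bin_ms = 20,
                                    window = c(0, 10)), "degenerate")
})

test_that("ISI statistics: CV near 1 for Poisson, 0 for clocks, dead-time oracle", {
  sp <- poisson_spikes(1, rate_hz = 20, t_max_ms = 3e5, seed = 5)
  st <- isi_stats(sp)
  expect_lt(abs(st$per_neuron$cv - 1), 0.05)
  # exponential tail fit recovers the rate (1/ms)
  expect_equal(st$exp_rate, 20 / 1000, tolerance = 0.1)

  periodic <- tibble::tibble(time_ms = seq(0, 10000, 100), neuron_id = 1L)
  expect_equal(isi_stats(periodic)$per_neuron$cv, 0)

  # Poisson with 5 ms dead time: CV slightly below 1, matching a direct
  # simulation of the thinned process
  thin_cv <- function(seed) {
    set.seed(seed)
    t <- cumsum(rexp(30000, 3 / 1000) + 5)
    isi <- diff(t)
    sd(isi) / mean(isi)
  }
  set.seed(6)
  t <- cumsum(rexp(30000, 3 / 1000) + 5)
  st2 <- isi_stats(tibble::tibble(time_ms = t, neuron_id = 1L))
  expect_lt(st2$per_neuron$cv, 1)
  expect_equal(st2$per_neuron$cv, mean(sapply(10:14, thin_cv)),
               tolerance = 0.02)

  # neurons with < 2 spikes are skipped
  st3 <- isi_stats(tibble::tibble(time_ms = c(1, 2, 3), neuron_id = c(1L, 1L, 2L)))
  expect_equal(st3$per_neuron$neuron_id, 1)
})

test_that("rate curves conserve kernel mass and peaks sit at burst times", {
  cl <- make_cl()
  # interior burst: mass equals the spike count, peak at the burst centre
  ids <- cl$neuron_id[cl$cluster == 3]
  sp <- tibble::tibble(time_ms = rep(250, 40), neuron_id = rep_len(ids, 40))
  rc <- cluster_rates(sp, cl, window = c(0, 500))
  r3 <- rc[rc$cluster == 3, ]
  expect_equal(sum(r3$rate) / 1000, 40, tolerance = 1e-6)
  expect_equal(firing_time(r3), 250, tolerance = 1)
  # clusters without spikes have flat-zero curves and no firing time
  r1 <- rc[rc$cluster == 1, ]
  expect_true(all(r1$rate == 0))
  expect_true(is.na(firing_time(r1)))
})

test_that("firing_time picks the first peak; plateaus resolve to midpoints", {
  # two bursts: the first peak wins even if the second is higher
  rc <- tibble::tibble(time_ms = seq(0.5, 500, 1), rate = 0)
  rc$rate <- dnorm(rc$time_ms, 100, 30) + 2 * dnorm(rc$time_ms, 300, 30)
  expect_equal(firing_time(rc), 100, tolerance = 1.5)
  # plateau midpoint
  rp <- tibble::tibble(time_ms = 1:11, rate = c(0, 1, 2, 3, 3, 3, 3, 2, 1, 0, 0))
  expect_equal(firing_time(rp), 5)  # plateau 4..7 -> midpoint index 5.5 -> 5
  # monotone curve: no interior maximum
  rm <- tibble::tibble(time_ms = 1:10, rate = 1:10)
  expect_true(is.na(firing_time(rm)))
})

test_that("replay scoring reproduces constructed order, reversal and shuffles", {
  cl <- make_cl()
  sp <- scripted_sequence_spikes(cl, n_trials = 6, separation_ms = 50)
  sc <- replay_scores(replay_times(sp, clusters = cl))
  expect_equal(sc$rho, rep(1, 6))
  expect_equal(sc$n_clusters, rep(8, 6))

  rev_sp <- scripted_sequence_spikes(cl, order = 8:1, n_trials = 4,
                                     separation_ms = 50)
  expect_equal(replay_scores(replay_times(rev_sp, clusters = cl))$rho,
               rep(-1, 4))
  # goal-to-start scoring flips the sign back
  expect_equal(replay_scores(replay_times(rev_sp, clusters = cl),
                             reverse = TRUE)$rho, rep(1, 4))

  # hand-computed tie-free example
  expect_equal(spearman_replay(c(10, 20, 30, 40), c(1, 2, 4, 3)), 0.8)
  expect_true(is.na(spearman_replay(c(10, NA, NA, NA), 1:4)))

  # shuffled orders: scores spread around zero over many trials
  set.seed(30)
  shuffled <- lapply(1:40, function(k) {
    s <- scripted_sequence_spikes(cl, order = sample(8), n_trials = 1,
                                  separation_ms = 50, seed = k)
    replay_scores(replay_times(s, clusters = cl))$rho
  })
  rho <- unlist(shuffled)
  expect_lt(abs(mean(rho)), 0.2)
  expect_gt(sd(rho), 0.3)
})

test_that("shift test: identity gives zero, location shift is detected", {
  set.seed(41)
  a <- runif(200, -1, 1)
  s0 <- shift_test(a, a)
  expect_equal(s0$delta_mean, 0)
  expect_equal(s0$ks_statistic, 0)

  s1 <- shift_test(a, a + 0.5)
  expect_equal(s1$delta_mean, 0.5)
  expect_lt(s1$p_value, 1e-6)

  # null calibration: KS p-values roughly uniform under the null
  ps <- vapply(1:40, function(k) {
    set.seed(k + 500)
    shift_test(rnorm(100), rnorm(100))$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.5), 0.25)
  expect_gt(min(ps), 1e-4)

  expect_error(shift_test(numeric(0), a), "empty")

  # tidiers
  td <- generics::tidy(s1)
  expect_equal(td$mean_rho[2] - td$mean_rho[1], 0.5)
  gl <- generics::glance(s1)
  expect_equal(gl$delta_mean, 0.5)
})

test_that("cross-correlograms detect constructed lags", {
  cl <- make_cl()
  # cluster bursts with 60 ms separation: mass at positive lags grows with
  # cluster distance
  sp <- scripted_sequence_spikes(cl, n_trials = 8, separation_ms = 60,
                                 jitter_ms = 5, seed = 9)
  fake <- structure(list(spikes = sp, clusters = cl), class = "sorn_experiment")
  sp2 <- sp; sp2$phase <- "test2"
  fake$spikes <- dplyr::bind_rows(sp, sp2)
  cg <- cluster_cross_correlogram(fake, bin_ms = 10, max_lag_ms = 250)
  expect_true(all(cg$before >= 0 & cg$before <= 1))
  # adjacent clusters: peak of the correlogram near +60 ms
  d1 <- cg[cg$distance == 1, ]
  expect_equal(d1$lag_ms[which.max(d1$before)], 60, tolerance = 10)
  # distance 3: peak near +180 ms
  d3 <- cg[cg$distance == 3, ]
  expect_equal(d3$lag_ms[which.max(d3$before)], 180, tolerance = 10)
})

test_that("transition probabilities count constructed peak sequences", {
  cl <- make_cl()
  idA <- cl$neuron_id[cl$cluster == 1][1]
  idB <- cl$neuron_id[cl$cluster == 2][1]
  # alternating A, B bursts 400 ms apart
  tms <- seq(200, 6200, by = 400)
  who <- rep(c(idA, idB), length.out = length(tms))
  sp <- tibble::tibble(time_ms = rep(tms, each = 8),
                       neuron_id = rep(who, each = 8))
  tp <- transition_probabilities(sp, cl, window = c(0, 6600))
  expect_equal(tp$matrix["A", "B"], 1)
  expect_equal(tp$matrix["B", "A"], 1)
  # rows with outgoing transitions sum to 1; silent clusters are NA
  expect_equal(sum(tp$matrix["A", ]), 1)
  expect_true(all(is.na(tp$matrix["C", ])))
  # the peak sequence matches construction
  expect_equal(tp$sequence$cluster,
               rep(c(1L, 2L), length.out = length(tms)))

  # forward/backward change summary on hand-built matrices
  m0 <- matrix(0, 8, 8); m1 <- m0
  m1[1, 2] <- 0.2; m1[2, 1] <- -0.1  # would-be change already in m1 - m0
  ch <- transition_change(m0, m1, max_span = 2)
  expect_equal(ch$mean_change[ch$direction == "forward"], 0.2 / 13)
  expect_equal(ch$mean_change[ch$direction == "backward"], -0.1 / 13)
})

test_that("recall speed recovers constructed speeds and filters by rho", {
  cl <- make_cl()
  cen <- attr(cl, "centers")
  spacing <- diff(cen$axis_pos)[1]
  sp <- scripted_sequence_spikes(cl, n_trials = 5, separation_ms = 50)
  tm <- replay_times(sp, clusters = cl)
  sc <- replay_scores(tm)
  rs <- recall_speed(tm, sc)
  expect_equal(nrow(rs), 5)
  expect_equal(rs$speed, rep(spacing / 50, 5), tolerance = 1e-6)

  # noisy firing times: slope recovered within the regression error
  set.seed(50)
  spj <- scripted_sequence_spikes(cl, n_trials = 10, separation_ms = 50,
                                  jitter_ms = 8, seed = 51)
  tmj <- replay_times(spj, clusters = cl)
  scj <- replay_scores(tmj)
  rsj <- recall_speed(tmj, scj)
  expect_gt(nrow(rsj), 2)
  expect_equal(mean(rsj$speed), spacing / 50, tolerance = 0.2 * spacing / 50)

  # equal firing times in a trial: undefined rank order, trial dropped
  ids <- cl$neuron_id[match(1:8, cl$cluster)]
  flat <- tibble::tibble(time_ms = rep(100, 8), neuron_id = ids,
                         phase = "test1", trial = 1L, t_rel = rep(100, 8))
  tf <- replay_times(flat, clusters = cl)
  sf <- replay_scores(tf)
  expect_equal(nrow(recall_speed(tf, sf)), 0)
})

test_that("match persistence counts threshold crossings per time bin", {
  before <- tibble::tibble(phase = "test1", trial = 1:50,
                           rho = rep(c(0.7, 0.1), 25))  # 50% matches
  # constructed decay: matches vanish after bin 2
  after <- tibble::tibble(phase = "test2", trial = 1:90,
                          rho = c(rep(0.95, 60), rep(0.0, 30)))
  mp <- match_persistence(before, after, threshold = 0.6, bin_s = 60,
                          period_ms = 2000)
  # 30 trials per 60-s bin: bins 1-2 all matches, bin 3 none
  expect_equal(mp$change, c(50, 50, -50))
  expect_equal(mp$t_mid_s, c(30, 90, 150))

  # identical distributions: zero change in every bin
  mp0 <- match_persistence(before, dplyr::mutate(before, trial = 1:50),
                           bin_s = 20, period_ms = 2000)
  expect_true(all(abs(mp0$change) < 1e-9))

  # all-match vs no-match: +100 points
  b0 <- tibble::tibble(trial = 1:10, rho = rep(0, 10))
  a1 <- tibble::tibble(trial = 1:10, rho = rep(1, 10))
  expect_equal(match_persistence(b0, a1, bin_s = 20)$change, 100)
})

test_that("weight-to-PSP conversion: zero maps to zero, classes use their kernels", {
  expect_equal(weight_to_psp(0, "EE"), 0)
  # excitatory: positive, driving force 60 mV, tau_e kernel
  p <- sorn_params()
  peak_e <- weight_to_psp(1, "EE")
  expect_gt(peak_e, 0)
  # inhibitory: negative, driving force -20 mV, tau_i kernel
  peak_i <- weight_to_psp(1, "II")
  expect_lt(peak_i, 0)
  # numerical maximization of the double-exponential kernel agrees
  num_peak <- function(tau, tau_s, drive) {
    tt <- seq(0.01, 200, 0.01)
    k <- (exp(-tt / tau) - exp(-tt / tau_s)) * tau_s / (tau - tau_s) *
      tau / (tau - tau_s)
    drive * max(k) * (tau - tau_s) / tau
  }
  expect_equal(peak_e, num_peak(20, 3, 60), tolerance = 1e-3)
  expect_equal(peak_i, num_peak(20, 5, -20), tolerance = 1e-3)
  # tau_s = tau limit uses t e^{-t/tau}: peak factor exp(-1)
  p_eq <- sorn_params(neuron = list(tau_i = 20))
  expect_equal(weight_to_psp(1, "II", p_eq), -20 * exp(-1))
})

test_that("adjacent-cluster weight summary averages per pair over existing synapses", {
  cl <- make_cl()
  a <- cl$neuron_id[cl$cluster == 1][1:2]
  b <- cl$neuron_id[cl$cluster == 2][1:2]
  c3 <- cl$neuron_id[cl$cluster == 3][1]
  syn <- tibble::tibble(
    pre = c(a[1], a[2], b[1], b[2]),
    post = c(b[1], b[2], c3, a[1]),
    weight = c(0.2, 0.4, 0.6, 0.8))
  acw <- adjacent_cluster_weights(syn, cl)
  # forward: pair 1->2 mean 0.3, pair 2->3 mean 0.6 -> average 0.45
  expect_equal(acw$mean_weight[acw$direction == "forward"], (0.3 + 0.6) / 2)
  # backward: only 2->1 with 0.8
  expect_equal(acw$mean_weight[acw$direction == "backward"], 0.8)
})
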