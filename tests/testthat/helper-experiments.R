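# Desk-scale experiment battery shared by the acceptance tests, built once
# per test run (see helper-cache.R). Sizes are the package's reduced study
# conditions, chosen once and documented in the methods vignette:
# half-density network (500 excitatory neurons) on the full-size sheet so
# the stimulus geometry is unchanged, structural growth scaled by
# (500/1000)^2, growth 250 s, test phases 60 s (30 trials), training 100 s
# (50 sweeps).

desk_net <- function(seed) make_mini_network(n_exc = 500, scale = 1,
                                             seed = seed)

desk_experiment <- function(variant, seed, v_spot = 4, mechanisms = list(),
                            extra_snapshots = numeric(0)) {
  key <- paste("exp", variant, seed, v_spot,
               paste(names(mechanisms), collapse = "."), sep = "_")
  cached(key, {
    net <- desk_net(seed)
    net$params$stimulus$v_spot <- v_spot
    pr <- sorn_protocol(variant, params = net$params, growth_s = 250,
                        test_s = 60, train_s = 100, relax_s = 10)
    run_experiment(net, pr, seed = 1000 + seed + 10 * (v_spot != 4),
                   mechanisms = mechanisms,
                   extra_snapshots = extra_snapshots)
  })
}

desk_scores <- function(ex, phase, reverse = FALSE) {
  replay_scores(replay_times(ex, phase), reverse = reverse)
}

desk_shift <- function(ex, reverse = FALSE) {
  s1 <- desk_scores(ex, "test1", reverse)
  s2 <- desk_scores(ex, "test2", reverse)
  mean(s2$rho, na.rm = TRUE) - mean(s1$rho, na.rm = TRUE)
}

# full-size noise-only run shared by the rate / irregularity / PSP checks
full_noise_sim <- function() {
  cached("full_noise", {
    net <- sorn_network(seed = 11)
    simulate_network(net, 150000, seed = 12)
  })
}
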