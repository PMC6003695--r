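# Tests of the compiled integration engine against closed forms and the
# R-level rule implementations.

mech_off <- list(stdp = FALSE, stp = FALSE, sn = FALSE, sp = FALSE,
                 ip = FALSE, noise = FALSE)

ee_factor <- function() factor("EE", levels = c("EE", "EI", "IE", "II"))

test_that("membrane dynamics match the closed-form linear ODE", {
  # resting fixed point: no input, no noise, V stays at E_L
  net <- sorn_network(n_exc = 3, n_inh = 0, seed = 1)
  sim <- simulate_network(net, 50, seed = 1, mechanisms = mech_off,
                          record_v = 1:3)
  expect_true(all(abs(sim$voltage$V + 60) < 1e-12))
  expect_equal(nrow(sim$spikes), 0)

  # exponential relaxation from -50 mV with tau = 20 ms
  net$state$V[] <- -50
  net$state$V_T[] <- 0  # out of reach
  sim <- simulate_network(net, 60, seed = 1, mechanisms = mech_off,
                          record_v = 1L)
  v20 <- sim$voltage$V[sim$voltage$time_ms == 20]
  expect_equal(v20, -60 + 10 * exp(-1), tolerance = 2e-3)

  # Euler error shrinks ~10x at dt/10 (first-order convergence)
  p_fine <- sorn_params(neuron = list(dt = 0.01))
  netf <- sorn_network(n_exc = 1, n_inh = 0, params = p_fine, seed = 1)
  netf$state$V[] <- -50; netf$state$V_T[] <- 0
  simf <- simulate_network(netf, 60, seed = 1, mechanisms = mech_off,
                           record_v = 1L)
  vf <- simf$voltage$V[abs(simf$voltage$time_ms - 20) < 1e-9]
  err_coarse <- abs(v20 - (-60 + 10 * exp(-1)))
  err_fine <- abs(vf - (-60 + 10 * exp(-1)))
  expect_lt(err_fine, err_coarse / 5)
})

test_that("synaptic delays are exact on the step grid", {
  # E->E delay 3 ms: presynaptic spike at t, conductance jump visible in
  # the postsynaptic membrane derivative from t + 3.0 exactly
  net <- sorn_network(n_exc = 2, n_inh = 0, seed = 2)
  net$synapses <- tibble::tibble(pre = 1L, post = 2L, weight = 1,
                                 class = ee_factor(), delay = 3)
  net$state$V[1] <- -10  # spikes in the first step (t = 0.1)
  sim <- simulate_network(net, 10, seed = 1, mechanisms = mech_off,
                          record_v = 2L)
  v <- sim$voltage
  # delivery at the end of step t = 3.1; first membrane response at 3.2
  expect_true(all(abs(v$V[v$time_ms <= 3.1] + 60) < 1e-12))
  expect_gt(v$V[abs(v$time_ms - 3.2) < 1e-9], -60)
})

test_that("noise-free runs with fixed seeds are bit-identical", {
  net <- make_mini_network(n_exc = 30, seed = 3)
  s1 <- simulate_network(net, 3000, seed = 5)
  s2 <- simulate_network(net, 3000, seed = 5)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$net$synapses, s2$net$synapses)
  expect_identical(s1$net$state, s2$net$state)
  # different seed diverges
  s3 <- simulate_network(net, 3000, seed = 6)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("conductances stay non-negative through a driven run", {
  net <- make_mini_network(n_exc = 40, seed = 4)
  blocks <- dplyr::bind_rows(lapply(seq(0, 4000, 500), stim_cue,
                                    at = c(100, 100), params = net$params))
  sim <- simulate_network(net, 5000, stimulus = blocks, seed = 7)
  st <- sim$net$state
  expect_true(all(st$g_e >= 0) && all(st$g_i >= 0) && all(st$g_ext >= 0))
  expect_true(all(st$u >= 0 & st$u <= 1))
  expect_true(all(st$x >= 0 & st$x <= 1))
})

test_that("single-spike deflection matches the weight_to_psp closed form", {
  for (w in c(0.2, 0.8)) {
    net <- sorn_network(n_exc = 2, n_inh = 0, seed = 1)
    net$synapses <- tibble::tibble(pre = 1L, post = 2L, weight = w,
                                   class = ee_factor(), delay = 3)
    net$state$V[1] <- -10
    sim <- simulate_network(net, 100, seed = 1, mechanisms = mech_off,
                            record_v = 2L)
    peak <- max(sim$voltage$V) + 60
    # closed form linearizes the driving force at E_L; the simulated peak
    # is slightly smaller because V moves towards E_e during the PSP
    expect_equal(peak, weight_to_psp(w, "EE"), tolerance = 0.05)
  }
  # inhibitory deflection: negative, tau_i kernel
  neti <- sorn_network(n_exc = 1, n_inh = 1, seed = 1)
  neti$synapses <- tibble::tibble(pre = 2L, post = 1L, weight = 0.4,
                                  class = factor("IE", levels = c("EE", "EI", "IE", "II")),
                                  delay = 2)
  neti$state$V[2] <- -10
  simi <- simulate_network(neti, 100, seed = 1, mechanisms = mech_off,
                           record_v = 1L)
  trough <- min(simi$voltage$V) + 60
  expect_equal(trough, weight_to_psp(0.4, "IE"), tolerance = 0.05)
})

test_that("online STDP equals the R replay of the recorded spikes", {
  # noisy mini network, fixed synapse structure (no SP/SN/IP), STDP on:
  # replaying the recorded spike train through apply_stdp() from the
  # initial weights must reproduce the engine's final weights
  set.seed(20)
  net <- make_mini_network(n_exc = 25, seed = 20)
  e <- 25
  pairs <- expand.grid(pre = 1:e, post = 1:e)
  pairs <- pairs[pairs$pre != pairs$post, ]
  idx <- sample(nrow(pairs), 120)
  ee0 <- tibble::tibble(pre = as.integer(pairs$pre[idx]),
                        post = as.integer(pairs$post[idx]),
                        weight = runif(120, 0.3, 1.5))
  net$synapses <- dplyr::bind_rows(
    tibble::tibble(pre = ee0$pre, post = ee0$post, weight = ee0$weight,
                   class = ee_factor(), delay = 3),
    net$synapses[net$synapses$class != "EE", ])
  sim <- simulate_network(net, 4000, seed = 21,
                          mechanisms = list(sn = FALSE, sp = FALSE,
                                            ip = FALSE))
  got <- sim$net$synapses[sim$net$synapses$class == "EE", c("pre", "post", "weight")]
  espikes <- sim$spikes[sim$spikes$neuron_id <= e, ]
  want <- apply_stdp(espikes, ee0, net$params, t_end = 4000)
  key_got <- paste(got$pre, got$post)
  key_want <- paste(want$pre, want$post)
  expect_setequal(key_got, key_want)
  expect_equal(unname(got$weight[order(key_got)]),
               unname(want$weight[order(key_want)]), tolerance = 1e-9)
  # and the engine agrees with the independent brute-force oracle too
  brute <- brute_stdp(espikes, ee0, net$params, t_end = 4000)
  expect_equal(unname(got$weight[order(key_got)]),
               unname(brute$weight[order(paste(brute$pre, brute$post))]),
               tolerance = 1e-9)
})

test_that("synaptic normalization in the engine hits each neuron's target", {
  net <- make_mini_network(n_exc = 40, seed = 30)
  sim <- simulate_network(net, 5000, seed = 31,
                          mechanisms = list(stdp = FALSE))
  ee <- sim$net$synapses[sim$net$synapses$class == "EE", ]
  sums <- tapply(ee$weight, ee$post, sum)
  target <- sim$net$w_total[as.integer(names(sums))]
  expect_equal(as.numeric(sums), unname(target), tolerance = 1e-9)
})

test_that("intrinsic plasticity drives the population towards its target rate", {
  sim <- cached("mini_noise_60s",
                simulate_network(make_mini_network(n_exc = 100, seed = 40),
                                 60000, seed = 41))
  tr <- sim$trace
  r_late <- mean(tr$rate_exc[tr$time_ms > 40000])
  expect_gt(r_late, 2); expect_lt(r_late, 4)
  # thresholds have individualized (spread reflects per-neuron adaptation)
  expect_gt(sd(sim$net$state$V_T[1:100]), 0.05)
})
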