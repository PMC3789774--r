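test_that("rate functions are nonnegative, continuous and give monotone m_inf", {
  v <- seq(-100, 60, by = 0.5)
  r <- hh_rate_functions(v)
  expect_true(all(as.matrix(r) >= 0))
  m_inf <- r$alpha_m / (r$alpha_m + r$beta_m)
  expect_true(all(diff(m_inf) > 0))
  # removable singularities at -40 mV (alpha_m) and -55 mV (alpha_n)
  expect_equal(hh_rate_functions(-40)$alpha_m, 1, tolerance = 1e-6)
  expect_equal(hh_rate_functions(-55)$alpha_n, 0.1, tolerance = 1e-6)
  eps <- 1e-9
  expect_equal(hh_rate_functions(-40 + eps)$alpha_m,
               hh_rate_functions(-40 - eps)$alpha_m, tolerance = 1e-6)
  # R and C++ implementations agree
  rc <- eibalance:::.hh_rates_cpp(-63.7)
  rr <- hh_rate_functions(-63.7)
  expect_equal(unname(rc), unname(unlist(rr)), tolerance = 1e-12)
})

test_that("deterministic resting state reproduces classic HH conductances", {
  p <- membrane_params()
  v_rest <- resting_potential(p)
  expect_equal(v_rest, -65, tolerance = 0.01)
  s <- hh_steady_state(v_rest)
  # quiescent deterministic integration stays at rest with no spikes
  tr <- integrate_compartment(p, NULL, duration = 50, deterministic = TRUE)
  expect_length(tr$spike_times, 0)
  expect_lt(abs(tr$v_final - v_rest), 0.01)
  expect_lt(max(abs(tr$voltage - v_rest)), 0.01)
  # resting conductances from the steady-state gating
  g_na_rest <- p$gbar_na * s$m_inf^3 * s$h_inf
  g_k_rest <- p$gbar_k * s$n_inf^4
  expect_equal(g_na_rest, p$gbar_na * mean(tr$p_open_na), tolerance = 1e-3)
  expect_equal(g_k_rest, p$gbar_k * mean(tr$p_open_k), tolerance = 1e-3)
})

test_that("deterministic mode matches an independent high-order ODE solution", {
  skip_if_not_installed("deSolve")
  p <- membrane_params()
  hh_ode <- function(t, y, parms) {
    r <- hh_rate_functions(y[1])
    g_e <- parms$g_e * 1e-3
    dv <- -(p$gbar_na * y[2]^3 * y[3] * (y[1] - p$e_na) +
            p$gbar_k * y[4]^4 * (y[1] - p$e_k) +
            p$g_leak * (y[1] - p$e_leak) +
            g_e * (y[1] - p$e_e)) / p$c_m
    list(c(dv,
           r$alpha_m * (1 - y[2]) - r$beta_m * y[2],
           r$alpha_h * (1 - y[3]) - r$beta_h * y[3],
           r$alpha_n * (1 - y[4]) - r$beta_n * y[4]))
  }
  v0 <- resting_potential(p)
  s0 <- hh_steady_state(v0)
  y0 <- c(v0, s0$m_inf, s0$h_inf, s0$n_inf)

  # subthreshold constant conductance: voltage agrees within 0.5 mV
  dur <- 50
  times <- seq(0, dur, by = 0.01)
  sol <- deSolve::lsoda(y0, times, hh_ode, parms = list(g_e = 2),
                        rtol = 1e-10, atol = 1e-10)
  tr <- integrate_compartment(p, NULL, duration = dur, deterministic = TRUE,
                              g_e = rep(2, dur / 0.01))
  expect_length(tr$spike_times, 0)
  expect_lt(max(abs(tr$voltage - sol[seq_along(tr$voltage), 2])), 0.5)

  # suprathreshold constant drive: same number of spikes, same rate
  dur <- 200
  times <- seq(0, dur, by = 0.01)
  sol <- deSolve::lsoda(y0, times, hh_ode, parms = list(g_e = 100),
                        rtol = 1e-10, atol = 1e-10)
  spikes_ode <- detect_spikes(sol[, 2], dt = 0.01)
  tr <- integrate_compartment(p, NULL, duration = dur, deterministic = TRUE,
                              g_e = rep(100, dur / 0.01))
  expect_equal(length(tr$spike_times), length(spikes_ode))
  expect_lt(max(abs(tr$spike_times - spikes_ode)), 1)  # < 1 ms timing shift

  # classic spike shape in the infinite-channel limit
  expect_gt(max(tr$voltage) - min(tr$voltage), 90)  # ~100 mV excursion
  above <- tr$voltage > -20
  width_ms <- mean(rle(above)$lengths[rle(above)$values]) * 0.01
  expect_lt(width_ms, 2)  # ~1 ms wide at half-ish height
})

test_that("markov stepping conserves channel counts and stays nonnegative", {
  p <- membrane_params()
  set.seed(1)
  st <- sample_channel_states(-65, p)
  expect_equal(sum(st$na), p$n_na)
  expect_equal(sum(st$k), p$n_k)
  na <- st$na; k <- st$k
  vs <- seq(-80, 20, length.out = 200)
  for (v in vs) {
    out <- markov_channel_step(na, k, v, 0.01)
    na <- out$na; k <- out$k
    expect_true(all(na >= 0) && all(k >= 0))
  }
  expect_equal(sum(na), p$n_na)
  expect_equal(sum(k), p$n_k)
  # oversized step is rejected rather than producing invalid probabilities
  expect_error(markov_channel_step(st$na, st$k, 40, 1), "reduce dt")
})

test_that("clamped-voltage equilibrium open fractions match steady-state gating", {
  p <- membrane_params()
  set.seed(2)
  st <- sample_channel_states(-30, p)
  out <- eibalance:::.markov_run_cpp(st$na, st$k, v = -30, dt = 0.01,
                                     n_steps = 50000)
  s <- hh_steady_state(-30)
  expect_equal(out[["k_open"]], s$n_inf^4, tolerance = 0.02)
  expect_equal(out[["na_open"]], s$m_inf^3 * s$h_inf, tolerance = 0.15)
})

test_that("spike detection handles fixtures and refractoriness", {
  dt <- 0.1
  v <- rep(-65, 3000)
  expect_length(detect_spikes(v, dt), 0)
  # three separated excursions above 0 mV
  v[c(201:215, 1001:1015, 2501:2515)] <- 30
  st <- detect_spikes(v, dt)
  expect_length(st, 3)
  expect_equal(st, c(20, 100, 250), tolerance = 1e-8)
  # two crossings within the lockout collapse to one
  v2 <- rep(-65, 100)
  v2[c(11:14, 21:24)] <- 10  # 1 ms and 2 ms events at dt = 0.1
  expect_length(detect_spikes(v2, dt, refractory = 2), 1)
  expect_length(detect_spikes(v2, dt, refractory = 0.5), 2)
})

test_that("frozen noise shares the stimulus but not the spike train", {
  p <- membrane_params()
  reg <- build_regime(60, 0.5, 0)
  tr1 <- integrate_compartment(p, reg, duration = 400, stimulus_seed = 5,
                               channel_seed = 1)
  tr2 <- integrate_compartment(p, reg, duration = 400, stimulus_seed = 5,
                               channel_seed = 2)
  expect_identical(tr1$g_e, tr2$g_e)
  expect_false(identical(tr1$spike_times, tr2$spike_times))
  expect_false(identical(tr1$voltage, tr2$voltage))
  # unfrozen: different stimulus seeds give different conductance waveforms
  tr3 <- integrate_compartment(p, reg, duration = 400, stimulus_seed = 6,
                               channel_seed = 1)
  expect_false(identical(tr1$g_e, tr3$g_e))
})

test_that("charge bookkeeping: C dV equals minus the integrated current", {
  p <- membrane_params()
  reg <- build_regime(40, 0.25, 1)
  tr <- integrate_compartment(p, reg, duration = 300, stimulus_seed = 1,
                              channel_seed = 3)
  lhs <- p$c_m * (tr$v_final - tr$voltage[1])
  rhs <- -tr$integrals$i_total
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # per-sample current balance on the recorded grid (Euler identity)
  i_tot <- tr$i_na + tr$i_k + tr$i_leak + tr$i_exc + tr$i_inh
  dv <- diff(tr$voltage)
  expect_equal(dv, -tr$dt / p$c_m * head(i_tot, -1), tolerance = 1e-10)
})

test_that("channel noise alone drives ~10 spikes/s in the quiescent compartment", {
  p <- membrane_params()
  rates <- vapply(1:5, function(i) {
    tr <- integrate_compartment(p, NULL, duration = 1000, channel_seed = i,
                                record_trace = FALSE)
    1000 * length(tr$spike_times) / tr$duration
  }, numeric(1))
  expect_gt(mean(rates), 3)
  expect_lt(mean(rates), 20)
})
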