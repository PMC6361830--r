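test_that("gate steady-state curves match their closed forms", {
  # independent route: both sigmoids are logistic functions
  v <- seq(-120, -30, by = 0.5)
  expect_equal(m_d_inf(v), plogis((v + 65) / 2), tolerance = 1e-12)
  expect_equal(h_d_inf(v), plogis(-(v + 65)), tolerance = 1e-12)

  expect_equal(m_d_inf(-65), 0.5)
  expect_equal(h_d_inf(-65), 0.5)
  expect_equal(m_d_inf(-50), 0.9994472214, tolerance = 1e-9)
  expect_equal(h_d_inf(-75), 0.9999546021, tolerance = 1e-9)
  expect_equal(h_d_inf(-50), 3.059022e-07, tolerance = 1e-5)
  # saturation and monotonicity
  expect_lt(m_d_inf(-100), 1e-7)
  expect_gt(h_d_inf(-100), 1 - 1e-7)
  expect_true(all(diff(m_d_inf(v)) > 0))
  # strict monotonicity away from double-precision saturation
  v_mid <- seq(-90, -40, by = 0.5)
  expect_true(all(diff(h_d_inf(v_mid)) < 0))
  expect_true(all(diff(h_d_inf(v)) <= 0))
  expect_error(m_d_inf(Inf))
})

test_that("membrane_rhs reproduces hand-evaluated currents", {
  p <- cell_params()
  # leak equilibrium: all other conductances silent at v = E_L
  st <- cell_state(v = p$E_L, m_d = 0, h_d = 1, s = 0)
  expect_equal(membrane_rhs(st, p)[["dv"]], 0)
  # at v = E_K the D-current vanishes: dv = -g_L (E_K - E_L) / C_m = +1
  st <- cell_state(v = p$E_K, m_d = 1, h_d = 1, s = 0)
  expect_equal(membrane_rhs(st, p)[["dv"]], -8 * (-90 + 65) / 200)
  expect_equal(membrane_rhs(st, p)[["dv"]], 1.0)
  # inhibition pulls toward E_Inh: N * g_Inh * (v - E_Inh)
  st <- cell_state(v = -50, m_d = 0, h_d = 0)
  d0 <- membrane_rhs(st, p)[["dv"]]
  d20 <- membrane_rhs(st, p, N_inh = 20)[["dv"]]
  expect_equal(d0 - d20, 20 * p$g_Inh * (-50 - p$E_Inh) / p$C_m)
  # non-finite state is rejected
  bad <- cell_state(); bad$v <- NaN
  expect_error(membrane_rhs(bad, p), "non-finite")
})

test_that("full resting equilibrium agrees with a root-finding oracle", {
  p <- cell_params()
  # oracle: 1-D root of the stationary current balance with gates at
  # steady state (frozen regression value -67.2706 mV)
  bal <- function(v) p$g_L * (v - p$E_L) +
    p$g_D * m_d_inf(v) * h_d_inf(v)^2 * (v - p$E_K)
  v_star <- uniroot(bal, c(-75, -55), tol = 1e-10)$root
  expect_equal(v_star, -67.27061668, tolerance = 1e-6)
  # simulated cell relaxes to the oracle equilibrium
  cfg <- network_config(n_cells = 1, params = p, t_max = 20000,
                        stimulus = stimulus_protocol(amplitude = 0))
  rec <- simulate_chain(cfg, record_cells = 1, record_dt = 100)
  tail_v <- tail(rec$trajectory$v, 5)
  expect_equal(tail_v, rep(v_star, 5), tolerance = 1e-3)
})

test_that("leak-only relaxation matches the analytic exponential", {
  # time constant C_m / g_L = 25 ms; all other currents disabled
  p <- cell_params(g_D = 0, g_Exc = 0, g_Excr = 0, g_Inh = 0)
  cfg <- network_config(n_cells = 1, params = p, t_max = 200,
                        stimulus = stimulus_protocol(amplitude = 0))
  rec <- simulate_chain(cfg, record_cells = 1, record_dt = 1)
  tr <- rec$trajectory
  v_exact <- p$E_L + (p$v_init - p$E_L) * exp(-tr$time / 25)
  expect_lt(max(abs(tr$v - v_exact)), 0.1)
})

test_that("gate relaxation at frozen voltage matches the closed form", {
  p <- cell_params()
  dt <- 0.05
  v <- -60
  h <- p$h_d0
  a <- exp(-dt / p$h_dtau)
  for (k in 1:4000) h <- h_d_inf(v) + (h - h_d_inf(v)) * a
  t <- 4000 * dt
  expect_equal(h, h_d_inf(v) + (p$h_d0 - h_d_inf(v)) * exp(-t / p$h_dtau),
               tolerance = 1e-6)
})

test_that("step_cell honours the spike contract and synaptic decay", {
  p <- cell_params()
  cfg <- integrator_config(dt = 0.05)
  # s decays exponentially between spikes: e^(-beta t), beta = 0.2
  st <- cell_state(v = p$E_L, m_d = 0, h_d = 1, s = 1)
  pq <- update_params(p, g_D = 0)   # keep v frozen at E_L
  for (k in 1:100) st <- step_cell(st, pq, cfg)$state   # 5 ms
  expect_equal(st$s, exp(-1), tolerance = 1e-12)
  # threshold crossing resets to v_R and s to 1
  st <- cell_state(v = -50.01, m_d = 1, h_d = 0, s = 0.5)
  out <- step_cell(st, p, cfg, s_pre = 1)   # strong drive pushes over V_T
  expect_true(out$spiked)
  expect_equal(out$state$v, p$v_R)
  expect_equal(out$state$s, 1)
})

test_that("trajectories are deterministic and gates stay in [0, 1]", {
  cfg <- network_config(n_cells = 5, t_max = 10000, stop_at_cell = 5)
  set.seed(99); r1 <- simulate_chain(cfg, noise = noise_config())
  set.seed(99); r2 <- simulate_chain(cfg, noise = noise_config())
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$first_spike, r2$first_spike)
  expect_gte(r1$gate_range[1], 0)
  expect_lte(r1$gate_range[2], 1)
})

test_that("integrator config validates its inputs", {
  expect_error(integrator_config(dt = 0))
  expect_error(integrator_config(dt = -1))
  expect_silent(integrator_config(dt = 0.01))
})
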