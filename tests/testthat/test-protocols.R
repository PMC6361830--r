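test_that("single-cell delays grow super-linearly with imposed inhibition", {
  res <- run_fig2_single_cell()
  d <- res$delays$delay
  expect_false(any(is.na(d)))
  expect_true(all(diff(d) > 0))          # strict ordering in N
  expect_gt(diff(d)[2], diff(d)[1])      # increments themselves increase
  # an uninhibited window fires far faster than the N = 20 window
  res0 <- run_fig2_single_cell(N_levels = c(0, 20),
                               window_starts = c(1000, 4000))
  d0 <- res0$delays$delay
  expect_lt(d0[1], d0[2])   # uninhibited firing comes sooner

  # h_d decays during the delay (slow inactivation carries the timer)
  tr <- res$trajectory
  win <- tr$time >= res$delays$onset[1] & tr$time <= res$delays$spike_time[1]
  expect_true(all(diff(tr$h_d[win]) < 0))
})

test_that("a window whose drive cannot overcome inhibition reports no spike", {
  res <- run_fig2_single_cell(amplitude = 2.5)
  expect_true(all(is.na(res$delays$delay)))
  expect_output(print(res), "no spike")
})

test_that("chain wave propagates with lengthening intervals", {
  rec <- run_fig3_chain(n_cells = 12, t_max = 40000)
  expect_true(rec$completed)
  isi <- activation_isi(rec)
  # the first few intervals shorten while the waiting cells' h_d settles
  # toward its subthreshold equilibrium; inhibition dominates thereafter
  expect_true(all(diff(isi[5:11]) > 0))
  expect_gt(isi[11], isi[1])
  expect_true(all(diff(rec$inhibition$N) >= 0))
  # slower D-current inactivation slows the whole wave
  rec1500 <- run_fig3_chain(n_cells = 12, h_dtau = 1500, t_max = 40000)
  expect_gt(rec$first_spike[12], rec1500$first_spike[12])
})

test_that("multi-trial runs are seeded, reproducible and exclusion-aware", {
  cfg <- network_config(n_cells = 6, t_max = 20000)
  # noise-off trials collapse onto the deterministic trajectory
  off <- noise_config(sd_gD = 0, sd_gExc = 0)
  ts <- run_trials(cfg, off, n_trials = 3, base_seed = 4)
  st <- scalar_stats(ts)
  expect_equal(st$sd, rep(0, nrow(st)))
  det <- simulate_chain(network_config(n_cells = 6, t_max = 20000,
                                       stop_at_cell = 6))
  expect_equal(st$mean, det$first_spike, tolerance = 1e-9)
  # same base seed, same records
  ts1 <- run_trials(cfg, noise_config(), n_trials = 4, base_seed = 21)
  ts2 <- run_trials(cfg, noise_config(), n_trials = 4, base_seed = 21)
  expect_identical(ts1$records, ts2$records)
  expect_equal(ts1$n_excluded, 0)
  # a chain that cannot propagate flags every trial
  dead_cfg <- network_config(n_cells = 2,
                             params = update_params(cell_params(), g_Exc = 0),
                             t_max = 3000)
  tsd <- run_trials(dead_cfg, off, n_trials = 2, base_seed = 1)
  expect_equal(tsd$n_excluded, 2)
  expect_true(all(tsd$records$cell == 1))
})

test_that("spike-time SD grows with cell index under trial noise", {
  cfg <- network_config(n_cells = 12, t_max = 60000)
  ts <- run_trials(cfg, noise_config(), n_trials = 30, base_seed = 8)
  st <- scalar_stats(ts)
  expect_gt(st$sd[st$cell == 12], st$sd[st$cell == 3])
  expect_true(all(diff(st$mean) > 0))
})

test_that("sweeps are reproducible from their spec and carry per-value stats", {
  cfg <- network_config(n_cells = 6, t_max = 30000)
  sp <- sweep_spec("h_dtau", c(1000, 1500), n_trials = 4, config = cfg,
                   base_seed = 5)
  sw1 <- run_sweep(sp)
  sw2 <- run_sweep(sp)
  expect_equal(sw1$stats[[1]]$mean, sw2$stats[[1]]$mean)
  expect_equal(length(sw1$stats), 2)
  # slower inactivation lengthens all mean spike times
  expect_true(all(sw1$stats[[2]]$mean > sw1$stats[[1]]$mean))
  expect_error(sweep_spec("not_a_param", 1), "unknown sweep parameter")
})

test_that("chain spike times converge with step refinement in relative terms", {
  f1 <- run_fig3_chain(n_cells = 8, t_max = 30000, dt = 0.05)$first_spike
  f2 <- run_fig3_chain(n_cells = 8, t_max = 30000, dt = 0.025)$first_spike
  expect_lt(max(abs(f1 - f2) / f2), 0.02)
})
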