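# Pure-R reference chain integrator built on step_cell(), mirroring the
# compiled core's update order: all cells advance serially (each reading
# its predecessor's already-updated synaptic variable), then threshold
# events are applied; silencing and the inhibition increment take effect
# from the next step. The cell-1 stimulus (conductance amp, reversal
# E_Exc) is injected as an equivalent feedforward s_pre = amp / g_Exc.
r_reference_chain <- function(params, n_cells, t_end, dt = 0.05,
                              amplitude = 4) {
  cfg <- integrator_config(dt = dt)
  states <- replicate(n_cells,
                      cell_state(v = params$v_init, m_d = params$m_d0,
                                 h_d = params$h_d0, s = 0),
                      simplify = FALSE)
  N <- 0
  first <- rep(NA_real_, n_cells)
  spikes <- list()
  stim_on <- TRUE
  n_steps <- round(t_end / dt)
  decay <- exp(-params$beta * dt)
  for (k in seq_len(n_steps) - 1L) {
    spiked <- logical(n_cells)
    # the compiled core applies spike resets after the whole sweep, so a
    # cell reads its predecessor's decayed but not-yet-reset s
    s_seen <- vapply(states, function(st) st$s * decay, numeric(1))
    for (i in seq_len(n_cells)) {
      s_pre <- if (i == 1) {
        if (stim_on) amplitude / params$g_Exc else 0
      } else s_seen[i - 1]
      st <- step_cell(states[[i]], params, cfg, s_pre = s_pre, N_inh = N)
      states[[i]] <- st$state
      spiked[i] <- st$spiked
    }
    tt <- (k + 1) * dt
    for (i in which(spiked)) {
      spikes[[length(spikes) + 1]] <- c(i, tt)
      if (is.na(first[i])) {
        first[i] <- tt
        N <- N + 1
        if (i > 1) states[[i - 1]]$firing <- FALSE
        if (i == 1) stim_on <- FALSE
      }
    }
  }
  sp <- do.call(rbind, spikes)
  list(first_spike = first,
       spikes = if (is.null(sp)) data.frame(cell = integer(), time = numeric())
                else data.frame(cell = sp[, 1], time = sp[, 2]))
}
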