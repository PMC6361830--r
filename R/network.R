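#' Stimulus protocol
#'
#' Describes the external drive applied to one cell, plus an optional
#' explicit inhibition schedule. The drive is a set of epochs; each epoch
#' is either a conductance-type excitatory drive `amplitude * (v - E_Exc)`
#' (the default, under which the published single-cell delays follow from
#' the published constants) or a raw current. With `clip_on_spike` an epoch
#' is switched off by the first spike of the target cell at or after the
#' epoch's onset — the "sustained step until the cell fires" protocol.
#'
#' @param amplitude drive amplitude (default 4), recycled across epochs.
#' @param onset epoch onset time(s), ms.
#' @param duration epoch duration(s), ms; `Inf` for a sustained step.
#' @param type `"conductance"` (reversal `E_Exc`) or `"current"`.
#' @param clip_on_spike logical; stop the epoch at the target's next spike.
#' @param target_cell 1-based index of the stimulated cell.
#' @param n_schedule optional data frame with columns `time`, `N`: a
#'   piecewise-constant override of the inhibition count (the value `N`
#'   applies from `time` onward). `NULL` (default) means `N` is counted
#'   dynamically: +1 at each cell's first spike.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' # sustained step at t = 0 until the first spike:
#' stimulus_protocol()
#' # the 10 ms square pulse variant:
#' stimulus_protocol(duration = 10, clip_on_spike = FALSE)
#' @export
stimulus_protocol <- function(amplitude = 4, onset = 0, duration = Inf,
                              type = c("conductance", "current"),
                              clip_on_spike = TRUE, target_cell = 1,
                              n_schedule = NULL) {
  type <- match.arg(type)
  n_ep <- max(length(onset), length(duration), length(amplitude))
  onset <- rep_len(onset, n_ep)
  duration <- rep_len(duration, n_ep)
  amplitude <- rep_len(amplitude, n_ep)
  stopifnot(all(is.finite(onset)), all(onset >= 0),
            all(duration > 0), all(is.finite(amplitude)),
            target_cell >= 1)
  if (!is.null(n_schedule)) {
    stopifnot(is.data.frame(n_schedule),
              all(c("time", "N") %in% names(n_schedule)),
              all(is.finite(n_schedule$time)), all(n_schedule$N >= 0),
              !is.unsorted(n_schedule$time))
  }
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 type = type, clip_on_spike = clip_on_spike,
                 target_cell = as.integer(target_cell),
                 n_schedule = n_schedule),
            class = "stimulus_protocol")
}

#' Chain network configuration
#'
#' Assembles the chain of time cells: cell `i` receives feedforward
#' excitation read from cell `i-1`'s synaptic variable, its own recurrent
#' self-excitation while it is in the persistent-firing regime, and the
#' common slow inhibition `N * g_Inh * (v - E_Inh)` where `N` counts the
#' cells that have fired. When cell `k` fires for the first time, `N`
#' increments and cell `k-1` is silenced (its recurrent drive is cleared,
#' so its synaptic variable decays away naturally and the successor still
#' sees the decaying tail).
#'
#' @param n_cells chain length (default 60; the chain-wave figure uses 40).
#' @param params shared [cell_params()] (optionally perturbed per cell by
#'   the noise layer at simulation time).
#' @param stimulus a [stimulus_protocol()] applied to cell 1.
#' @param dt integration step, ms.
#' @param t_max simulation horizon, ms. The default 150000 comfortably
#'   exceeds the ~60 s the default 60-cell wave needs.
#' @param stop_at_cell stop as soon as this cell fires (`NULL`: run to
#'   `t_max`). Running "until the activation of the target cell" is the
#'   multi-trial protocol's stopping rule.
#' @param recurrent,silencing logicals; disable for diagnostic runs.
#' @param seed optional integer seed consumed at simulation time.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_cells = 60, params = cell_params(),
                           stimulus = stimulus_protocol(), dt = 0.05,
                           t_max = 150000, stop_at_cell = NULL,
                           recurrent = TRUE, silencing = TRUE, seed = NULL) {
  stopifnot(is.numeric(n_cells), n_cells >= 1,
            inherits(params, "cell_params"),
            inherits(stimulus, "stimulus_protocol"),
            dt > 0, t_max > dt)
  n_cells <- as.integer(n_cells)
  if (!is.null(stop_at_cell))
    stopifnot(stop_at_cell >= 1, stop_at_cell <= n_cells)
  if (stimulus$target_cell > n_cells)
    stop("stimulus target cell exceeds chain length")
  structure(list(n_cells = n_cells, params = params, stimulus = stimulus,
                 dt = dt, t_max = t_max,
                 stop_at_cell = if (is.null(stop_at_cell)) 0L
                                else as.integer(stop_at_cell),
                 recurrent = isTRUE(recurrent), silencing = isTRUE(silencing),
                 seed = seed),
            class = "network_config")
}

#' Simulate one trial of the chain
#'
#' Runs the fixed-step integrator over the whole chain and returns the
#' complete spike record. A wave that dies (the stop cell never reaches
#' threshold before `t_max`) is reported via `completed = FALSE`, not an
#' error.
#'
#' @param config a [network_config()].
#' @param noise optional [noise_config()]; adds trial-wise conductance
#'   perturbations and/or Poisson presynaptic bombardment.
#' @param record_cells integer vector of cell indices whose state
#'   trajectories `(time, v, m_d, h_d, s)` are sampled every `record_dt`.
#' @param record_dt trajectory sampling interval, ms.
#' @return An object of class `spike_record`: a list with elements
#'   `spikes` (data frame `cell`, `time` — every spike), `first_spike`
#'   (per-cell first-spike times, `NA` if a cell never fired),
#'   `inhibition` (data frame `time`, `N`: the staircase of the inhibition
#'   count), `trajectory` (data frame or `NULL`), `completed`, `t_final`,
#'   `gate_range` (observed min/max over all gates — a boundedness check),
#'   and the conductance vectors actually used.
#' @examples
#' cfg <- network_config(n_cells = 3, t_max = 4000)
#' rec <- simulate_chain(cfg)
#' rec$first_spike
#' @export
simulate_chain <- function(config, noise = NULL,
                           record_cells = integer(0), record_dt = 1) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cells
  p <- config$params
  if (length(record_cells))
    stopifnot(all(record_cells >= 1), all(record_cells <= n))

  if (is.null(noise)) {
    gD <- rep(p$g_D, n); gE <- rep(p$g_Exc, n)
    g_noise <- 0; beta_n <- 0.1; n_presyn <- 0L; rate_hz <- 0
  } else {
    draws <- draw_conductances(p, noise, n_cells = n)
    gD <- draws$g_D; gE <- draws$g_Exc
    g_noise <- noise$g_noise; beta_n <- noise$beta_n
    n_presyn <- noise$n_presyn; rate_hz <- noise$rate_hz
  }

  st <- config$stimulus
  stim <- cbind(st$onset, st$onset + st$duration, st$amplitude)
  sched <- st$n_schedule
  dynamic <- is.null(sched)

  out <- cpp_simulate_chain(
    unclass(p), gD, gE, config$dt, config$t_max, config$stop_at_cell,
    stim, st$type == "conductance", isTRUE(st$clip_on_spike),
    st$target_cell, dynamic,
    if (dynamic) numeric(0) else as.numeric(sched$time),
    if (dynamic) numeric(0) else as.numeric(sched$N),
    config$recurrent, config$silencing,
    g_noise, beta_n, as.integer(n_presyn), rate_hz,
    if (length(record_cells)) record_dt else 0,
    as.integer(record_cells))

  structure(list(spikes = out$spikes,
                 first_spike = out$first_spike,
                 inhibition = out$inhibition,
                 trajectory = if (is.data.frame(out$trajectory))
                                out$trajectory else NULL,
                 completed = out$completed,
                 t_final = out$t_final,
                 gate_range = out$gate_range,
                 n_cells = n, dt = config$dt,
                 gD_cell = gD, gExc_cell = gE),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  nf <- sum(is.finite(x$first_spike))
  cat(sprintf("<spike_record> %d cells, %d spikes, %d cells activated\n",
              x$n_cells, nrow(x$spikes), nf))
  cat(sprintf("  completed: %s   t_final: %.1f ms\n", x$completed, x$t_final))
  if (nf > 1) {
    isi <- diff(x$first_spike[seq_len(nf)])
    cat(sprintf("  first-spike ISIs: %.0f ms (first) -> %.0f ms (last)\n",
                isi[1], isi[length(isi)]))
  }
  invisible(x)
}

#' Inter-activation intervals of a trial
#'
#' Differences between consecutive cells' first-spike times — the chain's
#' inter-spike interval (ISI) sequence, the quantity whose lengthening
#' carries the timing signal.
#'
#' @param record a `spike_record`.
#' @return Numeric vector of length `n_cells - 1` (NA past wave death).
#' @export
activation_isi <- function(record) {
  stopifnot(inherits(record, "spike_record"))
  diff(record$first_spike)
}
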