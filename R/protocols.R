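#' Single-cell delayed-firing protocol
#'
#' One continuous simulation of an isolated time cell under three (by
#' default) successive levels of imposed inhibition. Within each window the
#' inhibition count is clamped at `N_levels[i]`; a sustained step drive of
#' the given amplitude starts `input_offset` ms after the window opens and
#' is switched off by the cell's spike (or the window's end). The reported
#' delay is first-spike time minus drive onset: the time the D-current's
#' slow inactivation needs to give way under the imposed inhibition.
#' Synaptic connections play no role (an isolated cell), and the run is
#' noiseless.
#'
#' With default parameters the delays come out near 600, 800 and 1200 ms
#' for N = 20, 40 and 60 — increasing super-linearly with the inhibition
#' because the late stages of the exponential decay are slow.
#'
#' @param params a [cell_params()]; the default set applies (`h_dtau` =
#'   1500).
#' @param N_levels inhibition counts per window (default 20, 40, 60).
#' @param window_starts window opening times, ms.
#' @param window_length window length, ms.
#' @param input_offset drive onset relative to window opening, ms.
#' @param amplitude drive amplitude (conductance-type, default 4).
#' @param dt integration step, ms.
#' @param record_dt trajectory sampling interval (ms); the trajectory
#'   carries the `h_d` decay trace.
#' @return An object of class `fig2_result`: list with `delays` (data
#'   frame `N`, `onset`, `spike_time`, `delay`; `NA` spike time marks a
#'   window with no spike) and `trajectory`.
#' @examples
#' \donttest{
#' res <- run_fig2_single_cell()
#' res$delays
#' }
#' @export
run_fig2_single_cell <- function(params = cell_params(),
                                 N_levels = c(20, 40, 60),
                                 window_starts = c(1000, 4000, 7000),
                                 window_length = 3000,
                                 input_offset = 1000,
                                 amplitude = 4, dt = 0.05, record_dt = 1) {
  stopifnot(length(N_levels) == length(window_starts),
            all(diff(window_starts) >= window_length))
  onsets <- window_starts + input_offset
  sched <- data.frame(time = c(0, window_starts,
                               window_starts + window_length),
                      N = c(0, N_levels, rep(0, length(N_levels))))
  # when a window opens exactly where the previous one closes, the
  # opening level wins over the closing zero
  sched <- sched[order(sched$time, -sched$N), ]
  sched <- sched[!duplicated(sched$time), ]
  stim <- stimulus_protocol(amplitude = amplitude, onset = onsets,
                            duration = window_length - input_offset,
                            type = "conductance", clip_on_spike = TRUE,
                            target_cell = 1, n_schedule = sched)
  cfg <- network_config(n_cells = 1, params = params, stimulus = stim,
                        dt = dt, t_max = max(window_starts) + window_length,
                        recurrent = FALSE, silencing = FALSE)
  rec <- simulate_chain(cfg, record_cells = 1L, record_dt = record_dt)
  spk <- rec$spikes$time
  delays <- data.frame(N = N_levels, onset = onsets,
                       spike_time = NA_real_, delay = NA_real_)
  for (i in seq_along(onsets)) {
    hit <- spk[spk >= onsets[i] & spk < window_starts[i] + window_length]
    if (length(hit)) {
      delays$spike_time[i] <- hit[1]
      delays$delay[i] <- hit[1] - onsets[i]
    }
  }
  structure(list(delays = delays, trajectory = rec$trajectory,
                 record = rec),
            class = "fig2_result")
}

#' @export
print.fig2_result <- function(x, ...) {
  cat("<fig2_result> single-cell delayed firing under imposed inhibition\n")
  d <- x$delays
  for (i in seq_len(nrow(d)))
    cat(sprintf("  N = %2g : delay = %s ms\n", d$N[i],
                if (is.na(d$delay[i])) "no spike" else sprintf("%.1f", d$delay[i])))
  invisible(x)
}

#' Chain-wave protocol
#'
#' The deterministic chain-wave experiment: a chain (default 40 cells) with
#' slowed D-current inactivation (`h_dtau` = 3000 ms), no noise, kicked at
#' cell 1. Activity propagates cell to cell; accumulated inhibition makes
#' each successive inter-activation interval longer, and the inhibition
#' count traces a non-decreasing staircase.
#'
#' @param n_cells chain length (default 40).
#' @param params base [cell_params()]; `h_dtau` is overridden by the
#'   `h_dtau` argument.
#' @param h_dtau D-current inactivation time constant for this experiment
#'   (default 3000 ms).
#' @param t_max horizon, ms.
#' @param dt step, ms.
#' @param record_cells cells whose trajectories to record (default none).
#' @return A `spike_record` (see [simulate_chain()]); its `inhibition`
#'   element is the staircase trace.
#' @examples
#' \donttest{
#' rec <- run_fig3_chain(n_cells = 10)
#' activation_isi(rec)
#' }
#' @export
run_fig3_chain <- function(n_cells = 40, params = cell_params(),
                           h_dtau = 3000, t_max = 150000, dt = 0.05,
                           record_cells = integer(0)) {
  params <- update_params(params, h_dtau = h_dtau)
  cfg <- network_config(n_cells = n_cells, params = params,
                        stimulus = stimulus_protocol(), dt = dt,
                        t_max = t_max, stop_at_cell = n_cells)
  simulate_chain(cfg, record_cells = record_cells)
}

#' Multi-trial statistics protocol
#'
#' Repeats the chain simulation `n_trials` times with fresh noise draws,
#' each trial running until the target cell fires (or the horizon is hit).
#' Trial `i` seeds R's RNG with `base_seed + i`, so any single trial is
#' re-runnable in isolation and the whole set is reproducible from the
#' base seed. Trials whose wave dies before the target are flagged and
#' counted; their partial first-spike records are kept (a cell's statistics
#' use the trials in which that cell fired).
#'
#' @param config a [network_config()]; its `stop_at_cell` is overridden by
#'   `up_to_cell`.
#' @param noise a [noise_config()].
#' @param n_trials number of trials (the reference experiment uses 200).
#' @param up_to_cell run each trial until this cell fires (default: the
#'   whole chain). Records for any smaller target are identical by chain
#'   causality, so one run serves every target cell at once.
#' @param base_seed integer; trial `i` uses seed `base_seed + i`.
#' @param progress print a line every 25 trials.
#' @return An object of class `trial_set`: list with `records` (data frame
#'   `trial`, `cell`, `time` of first spikes), `completed` (logical per
#'   trial), `n_excluded`, `up_to_cell`, `n_trials`, `base_seed`.
#' @examples
#' \donttest{
#' cfg <- network_config(n_cells = 10)
#' ts <- run_trials(cfg, noise_config(), n_trials = 5, base_seed = 1)
#' scalar_stats(ts)
#' }
#' @export
run_trials <- function(config, noise = noise_config(), n_trials,
                       up_to_cell = config$n_cells, base_seed = 1,
                       progress = FALSE) {
  stopifnot(inherits(config, "network_config"), n_trials >= 1,
            up_to_cell >= 1, up_to_cell <= config$n_cells)
  config$stop_at_cell <- as.integer(up_to_cell)
  config$seed <- NULL
  recs <- vector("list", n_trials)
  completed <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(base_seed + i)
    r <- simulate_chain(config, noise = noise)
    fs <- r$first_spike[seq_len(up_to_cell)]
    keep <- is.finite(fs)
    recs[[i]] <- data.frame(trial = i, cell = which(keep), time = fs[keep])
    completed[i] <- r$completed
    if (progress && i %% 25 == 0)
      message(sprintf("trial %d/%d (%d excluded so far)",
                      i, n_trials, sum(!completed[seq_len(i)])))
  }
  structure(list(records = do.call(rbind, recs),
                 completed = completed,
                 n_excluded = sum(!completed),
                 up_to_cell = as.integer(up_to_cell),
                 n_trials = as.integer(n_trials),
                 base_seed = base_seed),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials to cell %d (base seed %s); %d excluded\n",
              x$n_trials, x$up_to_cell, format(x$base_seed), x$n_excluded))
  invisible(x)
}

#' Parameter-sweep specification
#'
#' @param parameter name of the swept quantity: any [cell_params()] field
#'   (e.g. `"h_dtau"`, `"g_D"`) or `"g_noise"`.
#' @param values numeric vector of parameter values.
#' @param n_trials trials per value.
#' @param config base [network_config()].
#' @param noise base [noise_config()].
#' @param up_to_cell target cell per trial.
#' @param base_seed base seed; value `j` uses `base_seed + (j-1) * 100000`
#'   as its trial-seed origin so trial seeds never collide across values.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, values, n_trials = 50,
                       config = network_config(),
                       noise = noise_config(),
                       up_to_cell = config$n_cells, base_seed = 1) {
  stopifnot(is.character(parameter), length(parameter) == 1,
            all(is.finite(values)), length(values) >= 1, n_trials >= 1)
  if (!(parameter %in% c(names(config$params), "g_noise")))
    stop("unknown sweep parameter: ", parameter)
  structure(list(parameter = parameter, values = values,
                 n_trials = as.integer(n_trials), config = config,
                 noise = noise, up_to_cell = as.integer(up_to_cell),
                 base_seed = base_seed),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Executes [run_trials()] for each value of the swept parameter and
#' summarizes each with [scalar_stats()]. The canonical sweeps are
#' `h_dtau` in \{500, 1000, 1500, 2000\}, `g_D` in \{3.6, 3.8, 4, 4.2\}
#' (both with conductance noise), and — with Poisson bombardment as the
#' only noise source — `g_noise` over 0.6, 0.8, 1 and 1.2 times
#' [g_noise_ref()].
#'
#' @param spec a [sweep_spec()].
#' @param progress passed to [run_trials()].
#' @return An object of class `sweep_result`: list with `parameter`,
#'   `values`, `stats` (one [scalar_stats()] data frame per value) and
#'   `n_excluded` per value.
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  stats <- vector("list", length(spec$values))
  excl <- integer(length(spec$values))
  for (j in seq_along(spec$values)) {
    v <- spec$values[j]
    cfg <- spec$config
    noi <- spec$noise
    if (spec$parameter == "g_noise") noi$g_noise <- v
    else cfg$params <- do.call(update_params,
                               c(list(cfg$params), setNames(list(v), spec$parameter)))
    ts <- run_trials(cfg, noi, spec$n_trials, spec$up_to_cell,
                     base_seed = spec$base_seed + (j - 1) * 100000,
                     progress = progress)
    stats[[j]] <- scalar_stats(ts)
    excl[j] <- ts$n_excluded
  }
  structure(list(parameter = spec$parameter, values = spec$values,
                 stats = stats, n_excluded = excl),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over {%s}\n", x$parameter,
              paste(format(x$values), collapse = ", ")))
  for (j in seq_along(x$values)) {
    st <- x$stats[[j]]
    cat(sprintf("  %s = %-8g asymptotic CV = %.3f (%d trials excluded)\n",
                x$parameter, x$values[j], attr(st, "cv_asymptotic"),
                x$n_excluded[j]))
  }
  invisible(x)
}
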