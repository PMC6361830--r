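#' Noise configuration
#'
#' The model's two stochastic ingredients: (i) normally perturbed maximal
#' conductances — `g_D ~ Normal(g_D, sd_gD)` and
#' `g_Exc ~ Normal(g_Exc, sd_gExc)`, truncated at 0 — redrawn every trial;
#' (ii) Poisson presynaptic bombardment: each cell receives `n_presyn`
#' independent units firing at `rate_hz`; a unit's synaptic variable `s_n`
#' jumps to 1 at each of its events and decays as
#' \eqn{ds_n/dt = -\beta_n s_n}, and the summed current is
#' \eqn{I_{noise} = g_{noise} \sum_n s_n (v - E_{Exc})}.
#'
#' @details
#' `draw = "per_trial"` (default) assigns one conductance draw per trial,
#' shared along the chain — the literal reading of "simulations were run by
#' assigning the maximal conductance values as normally distributed random
#' variables", and the structure that makes the scalar property emerge: a
#' trial-level conductance offset is amplified more by later cells (whose
#' firing margin has shrunk under accumulated inhibition), so the spike-time
#' SD grows in proportion to the mean. `draw = "per_cell"` gives every cell
#' an independent draw each trial; independent per-interval noise is
#' compressed by the square root of the cell count, and the CV then falls
#' with cell index — the package keeps this mode precisely so that contrast
#' can be demonstrated (see the vignette).
#'
#' Default magnitudes: the published SDs (1 for `g_D`, 5 for `g_Exc`) are
#' incompatible with a propagating wave: the `g_Exc` perturbation alone
#' would exceed the delayed-firing mechanism's entire firing-margin band
#' several times over, so virtually every trial would die mid-chain. The
#' defaults keep the published 1:5 ratio but scale both SDs by a common
#' factor (~1/33) into the regime the 60-cell wave can absorb with rare
#' propagation failures: `sd_gD = 0.03`, `sd_gExc = 0.15`. `g_noise = 0` by default:
#' the multi-trial statistics runs use conductance noise only, and
#' Poisson-only runs (the bombardment sweep) enable it explicitly. The
#' package's reference bombardment conductance is `g_noise_ref()`, chosen so
#' the mean bombardment conductance (`n_presyn * rate * s̄`, about 33 units
#' of summed activation) perturbs rather than dominates the firing margin.
#'
#' @param sd_gD SD of the per-trial draw of `g_D` (default 0.03; see
#'   Details).
#' @param sd_gExc SD of the per-trial draw of `g_Exc` (default 0.15; see
#'   Details).
#' @param draw `"per_trial"` (one draw shared by all cells) or
#'   `"per_cell"` (independent draws per cell).
#' @param g_noise maximal conductance of the bombardment synapses; 0
#'   disables the Poisson noise entirely.
#' @param beta_n decay rate of the bombardment synaptic variables (0.1 per
#'   ms).
#' @param n_presyn number of presynaptic Poisson units per cell (100).
#' @param rate_hz mean firing rate per unit (50 Hz).
#' @return An object of class `noise_config`.
#' @examples
#' noise_config()                      # conductance noise only
#' noise_config(sd_gD = 0, sd_gExc = 0, g_noise = g_noise_ref())
#' @export
noise_config <- function(sd_gD = 0.03, sd_gExc = 0.15,
                         draw = c("per_trial", "per_cell"),
                         g_noise = 0, beta_n = 0.1,
                         n_presyn = 100, rate_hz = 50) {
  draw <- match.arg(draw)
  stopifnot(sd_gD >= 0, sd_gExc >= 0, g_noise >= 0, beta_n > 0,
            n_presyn >= 0, rate_hz >= 0)
  structure(list(sd_gD = sd_gD, sd_gExc = sd_gExc, draw = draw,
                 g_noise = g_noise, beta_n = beta_n,
                 n_presyn = as.integer(n_presyn), rate_hz = rate_hz),
            class = "noise_config")
}

#' Reference bombardment conductance
#'
#' The package's default `g_noise` for Poisson-only noise runs. The
#' bombardment sweep uses the multiples 0.6, 0.8, 1 and 1.2 of this value.
#' @return A single number.
#' @export
g_noise_ref <- function() 0.005

#' Draw perturbed maximal conductances for one trial
#'
#' Returns per-cell `g_D` and `g_Exc` vectors drawn from the configured
#' normal distributions and truncated at 0 (conductances cannot be
#' negative; at the default SD/mean ratios truncation is rare). With
#' `draw = "per_trial"` a single draw is replicated along the chain; with
#' `draw = "per_cell"` each cell draws independently. Uses R's RNG: seed
#' upstream with `set.seed()` for reproducibility.
#'
#' @param base a [cell_params()] supplying the means.
#' @param noise a [noise_config()].
#' @param n_cells number of cells.
#' @return A list with numeric vectors `g_D` and `g_Exc` of length
#'   `n_cells`.
#' @examples
#' set.seed(1)
#' draw_conductances(cell_params(), noise_config(), n_cells = 3)
#' @export
draw_conductances <- function(base, noise, n_cells = 1) {
  stopifnot(inherits(base, "cell_params"), inherits(noise, "noise_config"),
            n_cells >= 1)
  k <- if (noise$draw == "per_trial") 1 else n_cells
  gD <- pmax(0, rnorm(k, base$g_D, noise$sd_gD))
  gE <- pmax(0, rnorm(k, base$g_Exc, noise$sd_gExc))
  list(g_D = rep_len(gD, n_cells), g_Exc = rep_len(gE, n_cells))
}

#' Generate Poisson presynaptic spike trains
#'
#' Event times for `n_units` independent Poisson units over `[0, t_end]`,
#' by exponential inter-event sampling. This is the R-level counterpart of
#' the bombardment process the compiled integrator draws internally (from
#' the same R RNG); it exists for inspection and for testing the process
#' statistics.
#'
#' @param n_units number of units.
#' @param rate_hz mean rate per unit (Hz).
#' @param t_end horizon (ms).
#' @return A list of numeric vectors of strictly increasing event times
#'   (ms), one per unit.
#' @examples
#' set.seed(1)
#' trains <- poisson_trains(3, 50, 1000)
#' lengths(trains)
#' @export
poisson_trains <- function(n_units, rate_hz, t_end) {
  stopifnot(n_units >= 0, rate_hz >= 0, t_end > 0)
  rate_ms <- rate_hz / 1000
  lapply(seq_len(n_units), function(i) {
    if (rate_ms == 0) return(numeric(0))
    tt <- numeric(0)
    t <- rexp(1, rate_ms)
    while (t <= t_end) {
      tt <- c(tt, t)
      t <- t + rexp(1, rate_ms)
    }
    tt
  })
}

#' Bombardment noise current
#'
#' \eqn{I_{noise} = g_{noise} \sum_n s_n (v - E_{Exc})}: always a
#' depolarizing (inward, negative) current for `v < E_Exc`.
#'
#' @param v membrane potential (mV).
#' @param s_n numeric vector of bombardment synaptic variables in \[0, 1\].
#' @param noise a [noise_config()].
#' @param E_Exc excitatory reversal potential.
#' @return The noise current (same sign convention as the other currents:
#'   it is subtracted inside the membrane equation's bracket).
#' @export
noise_current <- function(v, s_n, noise, E_Exc = 0) {
  stopifnot(inherits(noise, "noise_config"),
            all(s_n >= 0), all(s_n <= 1))
  noise$g_noise * sum(s_n) * (v - E_Exc)
}
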