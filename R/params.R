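#' Biophysical parameters of one time cell
#'
#' Constructs the full constant set for a single spikeless
#' integrate-and-fire time cell with leak, D-type potassium, excitatory and
#' inhibitory synaptic currents:
#' \deqn{C_m \frac{dv}{dt} = -(I_L + I_D + I_{Exc} + I_{Inh}) + I_{input} + I_{noise}}
#' with \eqn{I_D = g_D m_d h_d^2 (v - E_K)}, fast activation
#' \eqn{m_{d\infty}(v) = 1 - 1/(1+e^{(v+65)/2})} and slow inactivation
#' \eqn{h_{d\infty}(v) = 1/(1+e^{v+65})}. The membrane potential is reset to
#' `v_R` when it reaches the threshold `V_T`; each spike also resets the
#' cell's synaptic output variable `s` to 1, which then decays as
#' \eqn{ds/dt = -\beta s}.
#'
#' All quantities are in the model's internal unit system (mV, ms, and
#' conductance/current units consistent with a capacitance of 200); the
#' published parameter table mixes unit labels, so no unit conversion is
#' applied and the numerals are used as-is.
#'
#' @details
#' The default feedforward conductance `g_Exc = 5.5` is the one deliberate
#' departure from the published table (which lists 15): with the published
#' recurrent conductance a persistently firing cell holds its synaptic
#' variable near saturation, so `g_Exc = 15` delivers an effective drive of
#' roughly 12 conductance units to the next cell — far above the maximum
#' D-current brake (`g_D * (V_T - E_K)` = 160 current units at threshold) —
#' and the wave races through the chain in milliseconds with no lengthening
#' intervals. The single-cell delayed-firing experiment pins the operative
#' drive at about 4 conductance units (the stimulus amplitude); `g_Exc = 5.5`
#' with a near-saturated synaptic variable delivers that drive with a firing
#' margin that stays clear of the propagation-failure point over the full
#' 60-cell chain,
#' and with it the depicted seconds-scale chain dynamics. See the package
#' vignette for the full argument.
#'
#' @param C_m membrane capacitance (200).
#' @param g_L,E_L leak conductance (8) and reversal potential (-65 mV).
#' @param g_D,E_K D-current maximal conductance (4) and potassium reversal
#'   potential (-90 mV).
#' @param m_dtau,h_dtau activation and inactivation time constants of the
#'   D-current (0.6 ms and 1500 ms; the chain-wave experiment uses 3000 ms).
#' @param V_T spike threshold (-50 mV).
#' @param v_R reset potential (-85 mV).
#' @param v_init initial membrane potential (-75 mV).
#' @param g_Exc feedforward excitatory maximal conductance (5.5; see Details).
#' @param g_Excr recurrent (self) excitatory maximal conductance (50).
#' @param E_Exc excitatory reversal potential (0 mV).
#' @param beta synaptic decay rate (0.2 per ms).
#' @param g_Inh per-unit inhibitory conductance (0.02); the total inhibitory
#'   current is `N * g_Inh * (v - E_Inh)` where `N` counts activated cells.
#' @param E_Inh inhibitory reversal potential (-100 mV).
#' @param m_d0,h_d0 initial gate values (0 and 1: the D-current is fully
#'   primed in a resting neuron).
#'
#' @return An object of class `cell_params`: a validated named list.
#' @examples
#' p <- cell_params()
#' p$g_D
#' p2 <- cell_params(h_dtau = 3000)  # chain-wave configuration
#' @export
cell_params <- function(C_m = 200, g_L = 8, E_L = -65, g_D = 4, E_K = -90,
                        m_dtau = 0.6, h_dtau = 1500, V_T = -50, v_R = -85,
                        v_init = -75, g_Exc = 5.5, g_Excr = 50, E_Exc = 0,
                        beta = 0.2, g_Inh = 0.02, E_Inh = -100,
                        m_d0 = 0, h_d0 = 1) {
  p <- list(C_m = C_m, g_L = g_L, E_L = E_L, g_D = g_D, E_K = E_K,
            m_dtau = m_dtau, h_dtau = h_dtau, V_T = V_T, v_R = v_R,
            v_init = v_init, g_Exc = g_Exc, g_Excr = g_Excr, E_Exc = E_Exc,
            beta = beta, g_Inh = g_Inh, E_Inh = E_Inh,
            m_d0 = m_d0, h_d0 = h_d0)
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

validate_cell_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-numeric or non-finite cell parameter: ",
         paste(names(p)[!num], collapse = ", "))
  for (g in c("C_m", "g_L", "g_D", "g_Exc", "g_Excr", "g_Inh"))
    if (p[[g]] < 0) stop(g, " must be >= 0")
  for (tau in c("m_dtau", "h_dtau"))
    if (p[[tau]] <= 0) stop(tau, " must be > 0")
  if (p$C_m <= 0) stop("C_m must be > 0")
  if (p$v_R >= p$V_T) stop("reset potential v_R must lie below threshold V_T")
  for (g in c("m_d0", "h_d0"))
    if (p[[g]] < 0 || p[[g]] > 1) stop(g, " must lie in [0, 1]")
  invisible(p)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> time-cell biophysical constants\n")
  cat(sprintf("  membrane : C_m=%g g_L=%g E_L=%g  V_T=%g v_R=%g v_init=%g\n",
              x$C_m, x$g_L, x$E_L, x$V_T, x$v_R, x$v_init))
  cat(sprintf("  D-current: g_D=%g E_K=%g m_dtau=%g h_dtau=%g\n",
              x$g_D, x$E_K, x$m_dtau, x$h_dtau))
  cat(sprintf("  synapses : g_Exc=%g g_Excr=%g E_Exc=%g beta=%g\n",
              x$g_Exc, x$g_Excr, x$E_Exc, x$beta))
  cat(sprintf("  inhibition: g_Inh=%g E_Inh=%g\n", x$g_Inh, x$E_Inh))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced; unknown field
#' names are an error (guards against silent typos).
#'
#' @param params a [cell_params()] object.
#' @param ... named replacement values.
#' @return A validated `cell_params` object.
#' @examples
#' update_params(cell_params(), h_dtau = 3000)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cell_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown cell parameter(s): ", paste(unknown, collapse = ", "))
  do.call(cell_params, modifyList(unclass(params), repl))
}
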