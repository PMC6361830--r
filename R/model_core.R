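#' Steady-state activation of the D-current
#'
#' \eqn{m_{d\infty}(v) = 1 - 1/(1 + e^{(v+65)/2})}: a rising sigmoid, near
#' 0 at rest and saturating toward 1 with depolarization. The gate follows
#' it fast (time constant `m_dtau` ~ 0.6 ms), so the D-current switches on
#' as soon as the cell depolarizes; this is consistent with the prescribed
#' initial value `m_d0 = 0` for a resting neuron.
#'
#' @param v membrane potential (mV); vectorized.
#' @return Gate value(s) in \[0, 1\].
#' @examples
#' m_d_inf(-65)   # 0.5 at the half-activation point
#' @export
m_d_inf <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  1 - 1 / (1 + exp((v + 65) / 2))
}

#' Steady-state inactivation of the D-current
#'
#' \eqn{h_{d\infty}(v) = 1/(1 + e^{v+65})}: close to 1 at hyperpolarized
#' potentials (the current is primed by inhibition) and close to 0 when
#' depolarized (slow inactivation under excitation, time constant `h_dtau`).
#'
#' @param v membrane potential (mV); vectorized.
#' @return Gate value(s) in \[0, 1\].
#' @examples
#' h_d_inf(-65)   # 0.5 at the midpoint
#' @export
h_d_inf <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  1 / (1 + exp(v + 65))
}

#' Instantaneous state of one time cell
#'
#' @param v membrane potential (mV).
#' @param m_d,h_d D-current activation and inactivation gates in \[0, 1\].
#' @param s synaptic output variable in \[0, 1\].
#' @param firing logical; whether the cell is in its persistent-firing
#'   regime (its recurrent self-excitation is engaged).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(v = -75, m_d = 0, h_d = 1, s = 0, firing = FALSE) {
  stopifnot(is.finite(v), m_d >= 0, m_d <= 1, h_d >= 0, h_d <= 1,
            s >= 0, s <= 1, is.logical(firing))
  structure(list(v = v, m_d = m_d, h_d = h_d, s = s, firing = firing),
            class = "cell_state")
}

#' Right-hand side of the membrane and gate equations
#'
#' Evaluates the time derivatives of `(v, m_d, h_d)` for one cell:
#' \deqn{C_m \dot v = -[g_L(v-E_L) + g_D m_d h_d^2 (v-E_K) + I_{Exc}
#'   + N g_{Inh}(v-E_{Inh})] + I_{input} + I_{noise}}
#' where \eqn{I_{Exc} = g_{Exc} s_{pre} (v-E_{Exc}) + g_{Excr} s_{self}
#' (v-E_{Exc})}, and each gate relaxes as \eqn{\dot x = (x_\infty(v)-x)/x_\tau}.
#'
#' This is the reference (pure R) formulation used by the test-suite to
#' cross-check the compiled integrator; simulations use the C++ core.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param s_pre synaptic variable of the presynaptic (feedforward) cell.
#' @param N_inh inhibition count: number of activated cells contributing
#'   slow inhibition.
#' @param I_input applied input current.
#' @param I_noise noise current.
#' @return Named numeric vector `c(dv, dm_d, dh_d)` (per ms).
#' @examples
#' st <- cell_state(v = -65, m_d = 0, h_d = 1)
#' membrane_rhs(st, cell_params())  # leak equilibrium: dv = 0 at v = E_L
#' @export
membrane_rhs <- function(state, params, s_pre = 0, N_inh = 0,
                         I_input = 0, I_noise = 0) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "cell_params"))
  ok <- vapply(state[c("v", "m_d", "h_d", "s")], is.finite, logical(1))
  if (!all(ok)) stop("non-finite state value: ",
                     paste(names(ok)[!ok], collapse = ", "))
  p <- params
  v <- state$v
  s_self <- if (isTRUE(state$firing)) state$s else 0
  I_L <- p$g_L * (v - p$E_L)
  I_D <- p$g_D * state$m_d * state$h_d^2 * (v - p$E_K)
  I_Exc <- p$g_Exc * s_pre * (v - p$E_Exc) + p$g_Excr * s_self * (v - p$E_Exc)
  I_Inh <- N_inh * p$g_Inh * (v - p$E_Inh)
  c(dv = (-(I_L + I_D + I_Exc + I_Inh) + I_input + I_noise) / p$C_m,
    dm_d = (m_d_inf(v) - state$m_d) / p$m_dtau,
    dh_d = (h_d_inf(v) - state$h_d) / p$h_dtau)
}

#' Integrator configuration
#'
#' @param dt fixed time step (ms). The default 0.05 ms resolves the fastest
#'   state variable (`m_dtau` = 0.6 ms) with 12 steps per time constant.
#' @param method stepping-scheme label. `"euler_exp"` advances the membrane
#'   potential by explicit Euler and both gates plus the synaptic variable
#'   by exact exponential relaxation toward their voltage-frozen targets,
#'   which is what the stiff gap between `m_dtau` (0.6 ms) and `h_dtau`
#'   (seconds) calls for.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.05, method = "euler_exp") {
  stopifnot(is.numeric(dt), length(dt) == 1, is.finite(dt), dt > 0)
  method <- match.arg(method)
  structure(list(dt = dt, method = method), class = "integrator_config")
}

#' Advance one cell by one fixed step (reference implementation)
#'
#' Advances a single cell's state by `dt`: membrane potential by explicit
#' Euler, gates by exponential relaxation toward \eqn{x_\infty(v)}, and the
#' synaptic variable by exact decay \eqn{s \to s e^{-\beta dt}}. A
#' threshold crossing (`v >= V_T`) triggers the spike event: the potential
#' is reset to `v_R`, `s` is reset to 1, and the spike is reported.
#'
#' This mirrors the compiled network integrator step-for-step and exists so
#' tests can check the fast path against an independent R transcription.
#'
#' @inheritParams membrane_rhs
#' @param config an [integrator_config()].
#' @return A list with the advanced `state` (class `cell_state`) and
#'   logical `spiked`.
#' @export
step_cell <- function(state, params, config = integrator_config(),
                      s_pre = 0, N_inh = 0, I_input = 0, I_noise = 0) {
  d <- membrane_rhs(state, params, s_pre, N_inh, I_input, I_noise)
  dt <- config$dt
  p <- params
  v <- state$v + dt * d[["dv"]]
  m <- m_d_inf(v) + (state$m_d - m_d_inf(v)) * exp(-dt / p$m_dtau)
  h <- h_d_inf(v) + (state$h_d - h_d_inf(v)) * exp(-dt / p$h_dtau)
  s <- state$s * exp(-p$beta * dt)
  spiked <- v >= p$V_T
  firing <- state$firing
  if (spiked) {
    v <- p$v_R
    s <- 1
    firing <- TRUE
  }
  if (!all(is.finite(c(v, m, h, s))))
    stop("non-finite state after integration step (v=", v, ")")
  list(state = cell_state(v, m, h, s, firing), spiked = spiked)
}
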