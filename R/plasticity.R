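#' Back-propagating action potential waveform
#'
#' Double-exponential decay of the dendritic BPAP, with a fast component
#' (tau 1.2 ms, proportion 0.75) and a slow component (tau 10 ms,
#' proportion 0.25). The sharp peak and thin tail contrast with the slower
#' EPSP and underlie the timing asymmetry of calcium influx.
#'
#' @param t time since the postsynaptic spike (ms); vectorized
#' @param params \code{\link{plasticity_params}}
#' @param bpap_max peak amplitude (mV); defaults to the calibrated value
#' @return BPAP amplitude (mV)
#' @export
bpap <- function(t, params = plasticity_params(), bpap_max = params$bpap_max) {
  if (any(t < 0)) stop("t must be non-negative")
  t_s <- t / 1000
  bpap_max * (params$i_f_bpap * exp(-t_s / params$tau_f_bpap) +
              params$i_s_bpap * exp(-t_s / params$tau_s_bpap))
}

#' Excitatory postsynaptic potential waveform
#'
#' Double-exponential EPSP with fast (2 ms) and slow (20 ms) components in
#' equal proportion. Amplitude at the synapse scales with the synaptic
#' weight (\code{epsp_max = epsp_scale * weight} in the full model).
#'
#' @inheritParams bpap
#' @param epsp_max peak amplitude (mV)
#' @return EPSP amplitude (mV)
#' @export
epsp <- function(t, params = plasticity_params(), epsp_max = 1) {
  if (any(t < 0)) stop("t must be non-negative")
  t_s <- t / 1000
  epsp_max * (params$i_f_epsp * exp(-t_s / params$tau_f_epsp) +
              params$i_s_epsp * exp(-t_s / params$tau_s_epsp))
}

#' Calcium driving force through the NMDA receptor
#'
#' Voltage dependence of the calcium flux: a linear driving force toward
#' the calcium reversal potential (130 mV on the model scale) divided by a
#' magnesium-block term of Jahr-Stevens form,
#' \deqn{H(V) = -0.42 (V - V_r) / (1 + 0.6 e^{-0.09 (V - v_{shift})} [Mg]/3.57).}
#' With \code{v_shift = 65} the block exponential is evaluated on the
#' absolute membrane-potential scale (model rest = -65 mV absolute), which
#' makes H steeply increasing from rest through the BPAP voltage range --
#' the coincidence-detection regime. \code{v_shift = 0} gives the literal
#' shifted-scale reading and \code{product = TRUE} the literal product
#' reading; both are retained for comparison.
#'
#' @param v membrane potential at the synapse (mV, model scale; rest = 0)
#' @param mg magnesium concentration (mM)
#' @param v_shift block-term voltage offset (mV)
#' @param v_reversal calcium reversal potential (mV)
#' @param product use the product reading of the block term
#' @return driving force (dimensionless flux units); zero at
#'   \code{v = v_reversal}
#' @export
driving_force <- function(v, mg = 1, v_shift = .calibrated$v_shift,
                          v_reversal = 130, product = FALSE) {
  if (length(mg) > 1) {
    if (length(v) == 1) v <- rep(v, length(mg))
    return(vapply(seq_along(v), function(i)
      cpp_driving_force(v[i], mg[i], v_reversal, v_shift, product), 0))
  }
  cpp_driving_force(as.numeric(v), mg, v_reversal, v_shift, product)
}

#' NMDA calcium current
#'
#' Current through NMDA receptors \code{t} ms after a presynaptic spike:
#' a double-exponential channel activation times the voltage-dependent
#' driving force, \eqn{I = P_0 G (I_f e^{-t/\tau_f} + I_s e^{-t/\tau_s}) H(V)}.
#' Zero before the first presynaptic spike.
#'
#' @param t_since_pre time since the presynaptic spike (ms); \code{NA} or
#'   negative means no spike yet (returns 0)
#' @param v synapse-local membrane potential (mV)
#' @param params \code{\link{plasticity_params}}
#' @return calcium flux (uM/s)
#' @export
nmda_current <- function(t_since_pre, v, params = plasticity_params()) {
  out <- numeric(length(t_since_pre))
  ok <- !is.na(t_since_pre) & t_since_pre >= 0
  if (any(ok)) {
    t_s <- t_since_pre[ok] / 1000
    act <- params$nmda_i_f * exp(-t_s / params$nmda_tau_f) +
           params$nmda_i_s * exp(-t_s / params$nmda_tau_s)
    h <- driving_force(v, mg = params$mg, v_shift = params$v_shift,
                       v_reversal = params$v_reversal_ca,
                       product = params$h_product)
    if (length(h) == 1) h <- rep(h, sum(ok))
    out[ok] <- params$nmda_gain * act * h[seq_len(sum(ok))]
  }
  out
}

#' One Euler step of the synaptic calcium concentration
#'
#' \eqn{dCa/dt = I_{NMDA} - Ca/\tau_{Ca}}, with calcium floored at zero.
#'
#' @param ca calcium concentration (uM)
#' @param i_nmda NMDA calcium flux (uM/s)
#' @param dt timestep (s)
#' @param tau_ca calcium decay time constant (s)
#' @return updated calcium (uM)
#' @export
calcium_step <- function(ca, i_nmda, dt, tau_ca = 0.050) {
  if (dt <= 0) stop("dt must be positive")
  if (any(ca < 0)) stop("calcium must be non-negative")
  pmax(0, ca + dt * (i_nmda - ca / tau_ca))
}

#' Omega function of the calcium control hypothesis
#'
#' \deqn{\Omega(Ca) = sig((Ca-\alpha_2)\beta_2) - \Omega_{rate}\,
#'   sig((Ca-\alpha_1)\beta_1)}
#' with \eqn{sig(x) = e^x/(1+e^x)}. Calcium between the two thresholds
#' yields the depression plateau (about \eqn{-\Omega_{rate}}); calcium
#' above \eqn{\alpha_2} the potentiation plateau (about
#' \eqn{1-\Omega_{rate}}).
#'
#' @param ca calcium concentration (uM), vectorized
#' @param params \code{\link{plasticity_params}}
#' @return Omega (dimensionless)
#' @export
omega <- function(ca, params = plasticity_params()) {
  if (any(ca < 0)) stop("calcium must be non-negative")
  s <- function(x) 1 / (1 + exp(-x))
  s((ca - params$alpha2) * params$beta2) -
    params$omega_rate * s((ca - params$alpha1) * params$beta1)
}

#' Calcium-dependent learning rate
#'
#' Monotonically increasing rate \eqn{\eta(Ca) = 1/(p_1/(p_2 + Ca^{p_3}) +
#' p_4)} (1/s): weight change is slow at resting calcium and approaches
#' 1/s at micromolar calcium.
#'
#' @inheritParams omega
#' @return learning rate (1/s)
#' @export
eta_ca <- function(ca, params = plasticity_params()) {
  params$eta_scale /
    (params$eta_p1 / (params$eta_p2 + ca^params$eta_p3) + params$eta_p4)
}

#' One step of the calcium-controlled weight update
#'
#' \eqn{\dot W = \eta(Ca)(\kappa\,\Omega(Ca) - W)} where \eqn{\kappa} maps
#' the dimensionless Omega attractor onto weight units; the result is
#' clipped to the plasticity bounds.
#'
#' @param state list with elements \code{weight} and \code{calcium}
#' @param dt timestep (s)
#' @param params \code{\link{plasticity_params}}
#' @return state with updated weight
#' @export
weight_update <- function(state, dt, params = plasticity_params()) {
  w <- state$weight
  ca <- state$calcium
  w <- w + dt * eta_ca(ca, params) *
    (params$omega_to_weight_scale * omega(ca, params) - w)
  state$weight <- pmin(params$weight_max, pmax(params$weight_min, w))
  state
}

#' Pair-based STDP weight update
#'
#' Standard exponential pair rule used by the STDP-only synapse variant:
#' \eqn{\Delta w = A_+ e^{-\Delta t/\tau_+}} for pre-before-post
#' (\eqn{\Delta t > 0}) and \eqn{-A_- e^{\Delta t/\tau_-}} for
#' post-before-pre. The result is clipped to the weight bounds.
#'
#' @param w current weight
#' @param delta_t post minus pre spike time (ms)
#' @param params \code{\link{plasticity_params}} (fields \code{stdp_*})
#' @return updated weight
#' @export
stdp_pair_update <- function(w, delta_t, params = plasticity_params("stdp_only")) {
  dt_s <- delta_t / 1000
  dw <- ifelse(dt_s > 0,
               params$stdp_a_plus * exp(-dt_s / params$stdp_tau_plus),
               -params$stdp_a_minus * exp(dt_s / params$stdp_tau_minus))
  dw[delta_t == 0] <- 0
  pmin(params$weight_max, pmax(params$weight_min, w + dw))
}
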