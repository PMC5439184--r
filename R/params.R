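#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane parameters of the reservoir neurons. The defaults are the
#' standard cortical-microcircuit values: a 30 ms membrane time constant,
#' 1 MOhm membrane resistance, a steady background current of 13.5 nA
#' (which holds the resting neuron at 13.5 mV, just below the 15 mV firing
#' threshold), and absolute refractory periods of 3 ms (excitatory) and
#' 2 ms (inhibitory). Synaptic currents decay exponentially with
#' \code{tau_syn}.
#'
#' @param tau_m membrane time constant (s)
#' @param v_resting resting potential (mV); the model voltage scale is
#'   shifted so that rest is 0 mV
#' @param r_m membrane resistance (MOhm)
#' @param i_inject steady background current (nA)
#' @param v_thresh firing threshold (mV)
#' @param refractory_e,refractory_i absolute refractory periods (s)
#' @param tau_syn excitatory synaptic current decay time constant (s)
#' @param tau_syn_i inhibitory synaptic current decay time constant (s)
#' @return a list of class \code{neuron_params}
#' @export
neuron_params <- function(tau_m = 0.030, v_resting = 0, r_m = 1,
                          i_inject = 13.5, v_thresh = 15,
                          refractory_e = 0.003, refractory_i = 0.002,
                          tau_syn = 0.003, tau_syn_i = 0.006) {
  stopifnot(tau_m > 0, r_m > 0, tau_syn > 0, v_thresh > v_resting,
            refractory_e > 0, refractory_i > 0)
  structure(list(tau_m = tau_m, v_resting = v_resting, r_m = r_m,
                 i_inject = i_inject, v_thresh = v_thresh,
                 refractory_e = refractory_e, refractory_i = refractory_i,
                 tau_syn = tau_syn, tau_syn_i = tau_syn_i),
            class = "neuron_params")
}

# NMDA-pathway and learning-rate constants frozen by the calibration run
# (scripts/calibrate_table1.R); see the methods vignette for the procedure.
.calibrated <- list(
  nmda_gain  = 28.3202,      # uM/s per unit (trace x H)
  epsp_scale = 2.79842e8,    # mV of local depolarization per A of weight
  bpap_max   = 87.4672,      # mV
  nmda_i_f   = 0.887477,
  nmda_tau_f = 0.0195099,    # s
  nmda_tau_s = 0.0343736,    # s
  p_w        = 0.108232,     # conductance-weight coupling exponent
  v_shift    = 74.7158,      # mV, resting-frame offset of the Mg-block term
  eta_p1     = 0.016753,     # eta(Ca) = 1/(p1/(p2 + Ca^p3) + p4), 1/s
  eta_p2     = 2.44441e-5,
  eta_p3     = 4.5537,
  eta_p4     = 0.919703,
  kappa      = 1.70085e-7,   # Omega-to-weight scale
  eta_scale  = 0.05,         # global learning timescale factor
  nmda_trace_cap = 2.0,      # saturation of the summed channel activation
  bpap_u     = 0.5,          # BPAP attenuation used per somatic spike
  bpap_tau_rec = 0.25        # BPAP efficacy recovery time constant (s)
)

#' NMDAR plasticity parameters (calcium control hypothesis)
#'
#' Parameters of the calcium-controlled bidirectional plasticity model.
#' Synaptic calcium is driven by the NMDA current, whose magnitude depends
#' on a double-exponential channel activation restarted/summed on
#' presynaptic spikes and on the voltage-dependent driving force evaluated
#' at the synapse-local potential (EPSP + back-propagating action
#' potential). The weight relaxes toward \code{omega_to_weight_scale *
#' omega(Ca)} at the calcium-dependent rate \code{eta(Ca)}.
#'
#' Variants: \code{"full"} is the complete model; \code{"ltp_ltd_only"}
#' removes BPAPs (rate-based plasticity only, original thresholds);
#' \code{"ltp_ltd_adjusted"} removes BPAPs and retunes the calcium
#' thresholds (alpha1 = 0.3 uM, omega_rate = 0.3) to compensate;
#' \code{"stdp_only"} replaces the calcium machinery with a pair-based
#' exponential STDP rule.
#'
#' @param variant plasticity variant, see Details
#' @param alpha1,alpha2 calcium thresholds for depression / potentiation
#'   induction (uM)
#' @param beta1,beta2 sigmoid steepness of the Omega function (1/uM)
#' @param omega_rate depression rate of the Omega function
#' @param tau_ca calcium decay time constant (s)
#' @param weight_min,weight_max hard bounds on plastic weights (CSIM weight
#'   units, A)
#' @param omega_to_weight_scale kappa, weight units per Omega unit
#' @param trace_mode \code{"sum"}: NMDA/EPSP traces from successive
#'   presynaptic spikes superpose; \code{"restart"}: the latest spike
#'   restarts the trace
#' @param mg extracellular magnesium concentration (mM)
#' @param v_shift voltage offset (mV) at which the magnesium-block
#'   exponential is evaluated; 65 evaluates the block on the absolute
#'   membrane-potential scale (model rest = -65 mV absolute), 0 gives the
#'   literal shifted-scale reading
#' @param h_product evaluate the block term as a product instead of a
#'   denominator (literal reading of the printed driving-force formula)
#' @param ... overrides for the remaining waveform / NMDA / eta constants
#'   (see the vignette for the full list)
#' @return a list of class \code{plasticity_params}
#' @export
plasticity_params <- function(variant = c("full", "ltp_ltd_only",
                                          "ltp_ltd_adjusted", "stdp_only"),
                              alpha1 = 0.1, alpha2 = 0.4,
                              beta1 = 80, beta2 = 80, omega_rate = 0.4,
                              tau_ca = 0.050,
                              weight_min = 1.0e-9, weight_max = 6.5e-8,
                              omega_to_weight_scale = .calibrated$kappa,
                              trace_mode = c("sum", "restart"),
                              mg = 1, v_shift = .calibrated$v_shift,
                              h_product = FALSE, ...) {
  variant <- match.arg(variant)
  trace_mode <- match.arg(trace_mode)
  p <- list(
    variant = variant,
    alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
    omega_rate = omega_rate, tau_ca = tau_ca,
    weight_min = weight_min, weight_max = weight_max,
    omega_to_weight_scale = omega_to_weight_scale,
    # postsynaptic waveforms
    bpap_max = .calibrated$bpap_max,
    tau_f_bpap = 0.0012, i_f_bpap = 0.75, tau_s_bpap = 0.010, i_s_bpap = 0.25,
    epsp_scale = .calibrated$epsp_scale,
    tau_f_epsp = 0.002, i_f_epsp = 0.5, tau_s_epsp = 0.020, i_s_epsp = 0.5,
    # NMDA current
    nmda_gain = .calibrated$nmda_gain,
    nmda_i_f = .calibrated$nmda_i_f, nmda_i_s = 1 - .calibrated$nmda_i_f,
    nmda_tau_f = .calibrated$nmda_tau_f, nmda_tau_s = .calibrated$nmda_tau_s,
    p_w = .calibrated$p_w, w_ref = 3e-8,
    mg = mg, v_reversal_ca = 130, v_shift = v_shift, h_product = h_product,
    # eta(Ca) = 1 / (p1/(p2 + Ca^p3) + p4), 1/s
    eta_p1 = .calibrated$eta_p1, eta_p2 = .calibrated$eta_p2,
    eta_p3 = .calibrated$eta_p3, eta_p4 = .calibrated$eta_p4,
    eta_scale = .calibrated$eta_scale,
    nmda_trace_cap = .calibrated$nmda_trace_cap,
    bpap_u = .calibrated$bpap_u,
    bpap_tau_rec = .calibrated$bpap_tau_rec,
    trace_mode = if (trace_mode == "sum") 1L else 0L,
    no_bpap = FALSE,
    # pair-based STDP variant
    stdp_a_plus = 1.0e-9, stdp_a_minus = 1.05e-9,
    stdp_tau_plus = 0.020, stdp_tau_minus = 0.020
  )
  if (variant == "ltp_ltd_only") p$no_bpap <- TRUE
  if (variant == "ltp_ltd_adjusted") {
    p$no_bpap <- TRUE
    if (missing(alpha1)) p$alpha1 <- 0.3
    if (missing(omega_rate)) p$omega_rate <- 0.3
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown plasticity parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$alpha1 < p$alpha2, p$tau_ca > 0, p$weight_min < p$weight_max)
  structure(p, class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("NMDAR plasticity parameters (variant: ", x$variant, ")\n", sep = "")
  cat(sprintf("  Omega: alpha1=%.3g alpha2=%.3g beta=%g/%g rate=%.3g\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2, x$omega_rate))
  cat(sprintf("  calcium tau=%.3g s; weight bounds [%.3g, %.3g]\n",
              x$tau_ca, x$weight_min, x$weight_max))
  cat(sprintf("  NMDA gain=%.3g, tau_f/s=%.3g/%.3g s, kappa=%.3g\n",
              x$nmda_gain, x$nmda_tau_f, x$nmda_tau_s,
              x$omega_to_weight_scale))
  invisible(x)
}

# map a variant string to the engine code
variant_code <- function(variant) {
  switch(variant,
         off = 0L, full = 1L,
         ltp_ltd_only = 2L, ltp_ltd_adjusted = 2L,
         stdp_only = 3L,
         stop("unknown plasticity variant: ", variant))
}
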