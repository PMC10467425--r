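#' Neuron parameters for the adaptive exponential integrate-and-fire model
#'
#' Default parameter sets reproducing the regular-spiking somatic dynamics of
#' cortical pyramidal cells (excitatory class) and the fast-spiking dynamics
#' of interneurons (inhibitory class). The constant bias current `I` is a
#' network-level tuning knob: the shipped defaults were frozen from a grid
#' search selecting an unstimulated single-region local field potential (LFP)
#' with a spectral peak in the 8-12 Hz alpha band and mean firing rates in
#' 1-20 Hz (see the package vignette).
#'
#' @param type `"exc"` or `"inh"`.
#' @param ... named overrides for individual parameters.
#'
#' @return An object of class `tacs_neuron_params`: a named list with
#'   components `C` (membrane capacitance, pF), `v_reset` (mV), `E_L` (leak
#'   reversal, mV), `g_L` (leak conductance, nS), `a` (subthreshold
#'   adaptation, nS), `b` (spike-triggered adaptation, pA), `Delta_T` (slope
#'   factor, mV), `tau_w` (adaptation time constant, ms), `v_th` (spike
#'   initiation threshold, mV), `v_peak` (spike detection threshold, mV),
#'   `t_ref` (refractory period, ms), and `I` (constant bias current, pA).
#' @export
#' @examples
#' neuron_params("exc")
#' neuron_params("inh", I = 30)
neuron_params <- function(type = c("exc", "inh"), ...) {
  type <- match.arg(type)
  p <- if (type == "exc") {
    list(C = 104, v_reset = -53.0, E_L = -65.0, g_L = 4.3, a = -0.8,
         b = 65.0, Delta_T = 0.8, tau_w = 88.0, v_th = -52.0,
         v_peak = 0.0, t_ref = 2.0, I = .tuned$I_exc)
  } else {
    list(C = 59, v_reset = -54.0, E_L = -62.0, g_L = 2.9, a = 1.8,
         b = 61.0, Delta_T = 3.0, tau_w = 16.0, v_th = -42.0,
         v_peak = 0.0, t_ref = 2.0, I = .tuned$I_inh)
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_neuron_params(p)
  structure(p, class = "tacs_neuron_params", type = type)
}

validate_neuron_params <- function(p) {
  stopifnot(p$C > 0, p$g_L > 0, p$tau_w > 0, p$Delta_T > 0,
            p$v_reset < p$v_peak, p$t_ref >= 0)
  invisible(p)
}

#' Synapse parameters for conductance-based alpha synapses
#'
#' AMPA (excitatory) and GABA-A (inhibitory) synapses with alpha-function
#' conductance kernels peaking at the maximum conductance `gbar` at lag
#' `tau_syn` after the presynaptic spike. The three maximum conductances are
#' network-level tuning knobs frozen together with the bias currents (see
#' [neuron_params()]).
#'
#' @param ... named overrides.
#' @return An object of class `tacs_synapse_params`: named list with
#'   `g_AMPA`, `g_GABA`, `g_noise` (maximum conductances, nS), `E_AMPA`
#'   (0 mV), `E_GABA` (-85 mV), `tau_AMPA` (3.0 ms), `tau_GABA` (3.2 ms) and
#'   `noise_rate` (background Poisson rate per neuron, Hz).
#' @export
synapse_params <- function(...) {
  p <- list(g_AMPA = .tuned$g_AMPA, g_GABA = .tuned$g_GABA,
            g_noise = .tuned$g_noise, E_AMPA = 0.0, E_GABA = -85.0,
            tau_AMPA = 3.0, tau_GABA = 3.2, noise_rate = 2400)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown synapse parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  stopifnot(p$g_AMPA >= 0, p$g_GABA >= 0, p$g_noise >= 0,
            p$E_GABA < p$E_AMPA, p$tau_AMPA > 0, p$tau_GABA > 0)
  structure(p, class = "tacs_synapse_params")
}

# Working-point constants frozen from the tuning grid search (see vignette:
# unstimulated single-region LFP peak in 8-12 Hz, rates 1-20 Hz).
.tuned <- list(I_exc = 12, I_inh = 0, g_AMPA = 0.05, g_GABA = 1.0,
               g_noise = 0.08)
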