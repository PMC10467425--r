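#' Sample per-neuron stimulation amplitudes from a distribution
#'
#' Implements the stimulus construction: each neuron of a region receives a
#' sinusoidal current I_ext(t) = A_i * V * sin(2 pi f t), where A_i is an
#' i.i.d. draw from the region's empirical normal-component distribution
#' (inverse-CDF sampling over the stored samples). Negative amplitudes
#' encode anti-phase drive; V = 0 yields an identically zero current.
#'
#' @param dist a `tacs_dist` (or list of them, one per region).
#' @param V global intensity scaling constant (pA per field unit).
#' @param f stimulation frequency (Hz, > 0).
#' @param seed integer seed for the amplitude draws.
#' @param n_per_region number of neurons per region (default 100).
#' @return A `tacs_stimulus`: list with `amplitudes` (one value per neuron,
#'   regions concatenated), `V`, `f`, `seed`.
#' @export
#' @examples
#' d <- as_dist(make_theoretical_distribution("gaussian", 0.05, 1000, seed = 1))
#' s <- assign_stimulus(d, V = 100, f = 10, seed = 2)
#' length(s$amplitudes)
assign_stimulus <- function(dist, V, f, seed, n_per_region = 100L) {
  if (inherits(dist, "tacs_dist")) dist <- list(dist)
  stopifnot(all(vapply(dist, inherits, TRUE, "tacs_dist")))
  if (f <= 0) stop("stimulation frequency must be > 0")
  if (any(vapply(dist, function(d) length(d$samples), 1L) == 0))
    stop("empty distribution")
  set.seed(seed)
  amps <- unlist(lapply(dist, function(d) {
    # inverse-CDF over the empirical sample = resampling with replacement
    d$samples[sample.int(length(d$samples), n_per_region, replace = TRUE)]
  }))
  structure(list(amplitudes = amps, V = V, f = f, seed = seed),
            class = "tacs_stimulus")
}

#' Simulate the spiking network
#'
#' Forward-integrates the adaptive exponential integrate-and-fire dynamics
#' with conductance-based alpha synapses, Poisson background drive, delayed
#' spike delivery, and (optionally) the sinusoidal stimulation currents, at
#' a fixed step `dt`. Spike detection at v_peak with reset, spike-triggered
#' adaptation, and a 2 ms refractory clamp. The per-region LFP is the
#' signed sum of all recurrent synaptic currents in the region, returned
#' with the initial transient removed.
#'
#' @param model a `tacs_network`.
#' @param stim a `tacs_stimulus`, or NULL for a baseline run.
#' @param duration total simulated time (s).
#' @param dt integration step (ms; default 0.1).
#' @param seed integer seed (drives the Poisson background).
#' @param transient_cut initial segment discarded from the LFP (s,
#'   default 4).
#' @param lfp_absolute if TRUE, sum absolute synaptic currents instead of
#'   the signed sum (non-default variant).
#' @return A `tacs_sim`: list with `spikes` (data.frame neuron/time_ms,
#'   including the transient), `lfp` (regions x time matrix, pA),
#'   `dt` (ms), `duration`, `transient_cut` (s), `seed`, `stim`.
#' @export
simulate_network <- function(model, stim = NULL, duration = 50, dt = 0.1,
                             seed = 1, transient_cut = 4,
                             lfp_absolute = FALSE) {
  stopifnot(inherits(model, "tacs_network"))
  if (duration <= transient_cut) stop("duration must exceed transient_cut")
  n <- n_neurons(model)
  if (is.null(stim)) {
    A <- numeric(n); V <- 0; f <- 0
  } else {
    stopifnot(inherits(stim, "tacs_stimulus"))
    if (length(stim$amplitudes) != n)
      stop("stimulus amplitudes do not match the number of neurons")
    A <- stim$amplitudes; V <- stim$V; f <- stim$f
  }
  n_steps <- round(duration * 1000 / dt)
  transient_steps <- round(transient_cut * 1000 / dt)
  delay_steps <- matrix(as.integer(round(model$delay_inter / dt)),
                        model$n_regions, model$n_regions)
  syn <- list(EA = model$syn$E_AMPA, EG = model$syn$E_GABA,
              tauA = model$syn$tau_AMPA, tauG = model$syn$tau_GABA,
              gA = model$syn$g_AMPA, gG = model$syn$g_GABA,
              g_noise = model$syn$g_noise, noise_rate = model$syn$noise_rate)
  set.seed(seed)
  res <- simulate_aeif_cpp(param_matrix(model), neuron_region(model),
                           neuron_is_exc(model), model$n_regions, syn,
                           model$G_inter, delay_steps,
                           as.integer(round(model$delay_intra / dt)),
                           A, V, f, as.integer(n_steps), dt,
                           as.integer(transient_steps), lfp_absolute)
  structure(list(spikes = data.frame(neuron = res$spike_neuron,
                                     time_ms = res$spike_time),
                 lfp = res$lfp, dt = dt, duration = duration,
                 transient_cut = transient_cut, seed = seed, stim = stim,
                 n_regions = model$n_regions,
                 n_per_region = model$n_exc + model$n_inh),
            class = "tacs_sim")
}

#' @export
print.tacs_sim <- function(x, ...) {
  cat(sprintf("tacs_sim: %d region(s), %.3g s (transient %.3g s cut), dt = %g ms, %d spikes\n",
              x$n_regions, x$duration, x$transient_cut, x$dt, nrow(x$spikes)))
  invisible(x)
}

#' Extract a region's local field potential
#'
#' @param result a `tacs_sim`.
#' @param region region index (1-based).
#' @return Numeric LFP time series (pA) with the transient removed.
#' @export
compute_lfp <- function(result, region = 1L) {
  stopifnot(inherits(result, "tacs_sim"))
  if (region < 1 || region > nrow(result$lfp)) stop("unknown region")
  result$lfp[region, ]
}

#' Mean firing rate per neuron class
#'
#' @param result a `tacs_sim`.
#' @param model the `tacs_network` that produced it.
#' @return Named numeric: mean rates (Hz) of excitatory and inhibitory
#'   neurons over the post-transient window.
#' @export
firing_rates <- function(result, model) {
  stopifnot(inherits(result, "tacs_sim"), inherits(model, "tacs_network"))
  window_s <- result$duration - result$transient_cut
  sp <- result$spikes[result$spikes$time_ms >= result$transient_cut * 1000, ]
  is_exc <- neuron_is_exc(model)
  n_exc_tot <- sum(is_exc); n_inh_tot <- sum(!is_exc)
  exc_sp <- sum(is_exc[sp$neuron]); inh_sp <- sum(!is_exc[sp$neuron])
  c(exc = exc_sp / n_exc_tot / window_s, inh = inh_sp / n_inh_tot / window_s)
}
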