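# Small populations for fast engine tests; full-size tuned node for the
# entrainment checks.
tiny_population <- function(n_exc = 8L, n_inh = 2L, I_exc = 0, I_inh = 0,
                            g_noise = 0, ...) {
  build_population(exc_params = neuron_params("exc", I = I_exc),
                   inh_params = neuron_params("inh", I = I_inh),
                   syn = synapse_params(g_noise = g_noise, ...),
                   n_exc = n_exc, n_inh = n_inh)
}

# A fake simulation result wrapping known LFP rows (for metric tests).
fake_sim <- function(lfp, dt = 0.1, transient_cut = 0) {
  structure(list(spikes = data.frame(neuron = integer(0), time_ms = numeric(0)),
                 lfp = lfp, dt = dt,
                 duration = transient_cut + ncol(lfp) * dt / 1000,
                 transient_cut = transient_cut, seed = 0, stim = NULL,
                 n_regions = nrow(lfp), n_per_region = 100L),
            class = "tacs_sim")
}
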