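#' Build a single-region spiking population
#'
#' One region is a balanced, fully-connected (all-to-all, no autapses)
#' network of 80 excitatory and 20 inhibitory adaptive exponential
#' integrate-and-fire neurons. Excitatory neurons project AMPA synapses to
#' every other neuron; inhibitory neurons project GABA-A synapses. The
#' intra-regional synaptic delay is 1.0 ms. Every neuron additionally
#' receives an independent 2.4 kHz Poisson background train onto AMPA-type
#' synapses with conductance `g_noise`.
#'
#' @param exc_params,inh_params `tacs_neuron_params` for the two classes.
#' @param syn a `tacs_synapse_params`.
#' @param n_exc,n_inh population sizes (defaults 80 / 20).
#' @return A `tacs_network` with a single region.
#' @export
#' @examples
#' net <- build_population()
#' net$n_exc; net$n_inh
build_population <- function(exc_params = neuron_params("exc"),
                             inh_params = neuron_params("inh"),
                             syn = synapse_params(),
                             n_exc = 80L, n_inh = 20L) {
  validate_neuron_params(exc_params)
  validate_neuron_params(inh_params)
  new_network(n_regions = 1L, exc_params = exc_params,
              inh_params = inh_params, syn = syn,
              G_inter = matrix(0, 1, 1), delay_inter = matrix(0, 1, 1),
              omega = 0, n_exc = as.integer(n_exc), n_inh = as.integer(n_inh))
}

#' Build a multi-region spiking network from a connectome
#'
#' Couples single-region populations through long-range excitatory (AMPA)
#' projections. Every excitatory neuron of region k' projects to every
#' neuron of region k with maximum conductance
#' `omega * w_kk' / max(w) * g_AMPA`, where w is the connectome weight
#' matrix; inhibitory neurons do not project between regions. The
#' inter-regional delay is the fiber length divided by the conduction speed
#' (default 3.9 m/s, giving roughly 4-46 ms for 15-180 mm tracts), quantized
#' to the integration grid at simulation time.
#'
#' @param connectome a `tacs_connectome` (symmetric, zero diagonal).
#' @param omega global coupling factor (>= 0).
#' @param conduction_speed axonal conduction speed (m/s, > 0).
#' @param exc_params,inh_params,syn parameter sets as in
#'   [build_population()].
#' @param n_exc,n_inh per-region population sizes.
#' @return A `tacs_network` with one population per connectome region.
#' @export
build_network <- function(connectome, omega, conduction_speed = 3.9,
                          exc_params = neuron_params("exc"),
                          inh_params = neuron_params("inh"),
                          syn = synapse_params(),
                          n_exc = 80L, n_inh = 20L) {
  stopifnot(inherits(connectome, "tacs_connectome"))
  W <- connectome$weights
  L <- connectome$lengths
  if (!isTRUE(all.equal(W, t(W))) || !isTRUE(all.equal(L, t(L))))
    stop("connectome weight/length matrices must be symmetric")
  if (any(diag(W) != 0) || any(W < 0)) stop("invalid connectome weights")
  if (omega < 0) stop("omega must be >= 0")
  if (conduction_speed <= 0) stop("conduction_speed must be > 0")
  validate_neuron_params(exc_params)
  validate_neuron_params(inh_params)

  K <- nrow(W)
  wmax <- max(W)
  G_inter <- if (wmax > 0) omega * W / wmax * syn$g_AMPA else matrix(0, K, K)
  # delay (ms) = length (mm) / speed (m/s);  mm / (m/s) = ms
  delay_inter <- L / conduction_speed
  new_network(n_regions = K, exc_params = exc_params, inh_params = inh_params,
              syn = syn, G_inter = G_inter, delay_inter = delay_inter,
              omega = omega, n_exc = as.integer(n_exc),
              n_inh = as.integer(n_inh),
              region_ids = connectome$region_ids)
}

new_network <- function(n_regions, exc_params, inh_params, syn, G_inter,
                        delay_inter, omega, n_exc = 80L, n_inh = 20L,
                        region_ids = seq_len(n_regions)) {
  structure(list(n_regions = as.integer(n_regions),
                 region_ids = region_ids,
                 n_exc = n_exc, n_inh = n_inh,
                 exc_params = exc_params, inh_params = inh_params,
                 syn = syn, omega = omega,
                 G_inter = G_inter, delay_inter = delay_inter,
                 delay_intra = 1.0),
            class = "tacs_network")
}

#' @export
print.tacs_network <- function(x, ...) {
  cat(sprintf("tacs_network: %d region(s) x (%dE + %dI) neurons, omega = %g\n",
              x$n_regions, x$n_exc, x$n_inh, x$omega))
  invisible(x)
}

n_neurons <- function(model) model$n_regions * (model$n_exc + model$n_inh)

# Flat per-neuron parameter matrix for the C++ engine.
param_matrix <- function(model) {
  pe <- model$exc_params; pi_ <- model$inh_params
  ord <- c("C", "g_L", "E_L", "a", "b", "Delta_T", "tau_w", "v_th",
           "v_peak", "v_reset", "t_ref", "I")
  rowE <- unlist(pe[ord]); rowI <- unlist(pi_[ord])
  mk_rows <- function(row, n)
    if (n > 0) matrix(row, n, 12, byrow = TRUE) else matrix(numeric(0), 0, 12)
  per_region <- rbind(mk_rows(rowE, model$n_exc), mk_rows(rowI, model$n_inh))
  P <- do.call(rbind, rep(list(per_region), model$n_regions))
  colnames(P) <- ord
  P
}

neuron_region <- function(model)
  rep(seq_len(model$n_regions) - 1L, each = model$n_exc + model$n_inh)

neuron_is_exc <- function(model)
  rep(rep(c(TRUE, FALSE), c(model$n_exc, model$n_inh)), model$n_regions)

#' Serialize / restore a network model
#'
#' `network_to_list()` converts a `tacs_network` to plain R lists (suitable
#' for `jsonlite::write_json`); `network_from_list()` reverses it exactly.
#'
#' @param model a `tacs_network`.
#' @return `network_to_list()`: a plain list; `network_from_list()`: a
#'   `tacs_network` identical to the serialized one.
#' @export
network_to_list <- function(model) {
  stopifnot(inherits(model, "tacs_network"))
  list(n_regions = model$n_regions, region_ids = model$region_ids,
       n_exc = model$n_exc, n_inh = model$n_inh,
       exc_params = unclass(model$exc_params),
       inh_params = unclass(model$inh_params),
       syn = unclass(model$syn), omega = model$omega,
       G_inter = as.vector(model$G_inter),
       delay_inter = as.vector(model$delay_inter),
       delay_intra = model$delay_intra)
}

#' @rdname network_to_list
#' @param x a list produced by `network_to_list()` (possibly via JSON).
#' @export
network_from_list <- function(x) {
  K <- as.integer(x$n_regions)
  new_network(n_regions = K, region_ids = unlist(x$region_ids),
              exc_params = structure(lapply(x$exc_params, as.numeric)[names(x$exc_params)],
                                     names = names(x$exc_params),
                                     class = "tacs_neuron_params"),
              inh_params = structure(lapply(x$inh_params, as.numeric),
                                     names = names(x$inh_params),
                                     class = "tacs_neuron_params"),
              syn = structure(lapply(x$syn, as.numeric), names = names(x$syn),
                              class = "tacs_synapse_params"),
              omega = as.numeric(x$omega),
              G_inter = matrix(unlist(x$G_inter), K, K),
              delay_inter = matrix(unlist(x$delay_inter), K, K),
              n_exc = as.integer(x$n_exc), n_inh = as.integer(x$n_inh))
}
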