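test_that("stimulus amplitudes resample the empirical distribution", {
  d <- as_dist(rep(0.7, 50))
  s <- assign_stimulus(d, V = 10, f = 10, seed = 1, n_per_region = 30)
  expect_true(all(s$amplitudes == 0.7))
  expect_length(s$amplitudes, 30)
  expect_error(assign_stimulus(as_dist(numeric(0)), 1, 10, 1), "empty")
  expect_error(assign_stimulus(d, 1, f = 0, seed = 1), "frequency")
  expect_identical(assign_stimulus(d, 1, 10, 3)$amplitudes,
                   assign_stimulus(d, 1, 10, 3)$amplitudes)
})

test_that("zero-mean symmetric drive splits neurons evenly into anti-phase", {
  d <- as_dist(make_theoretical_distribution("bimodal_symmetric", 0, 1e4, 1))
  p_src <- mean(d$samples < 0)
  expect_lt(abs(p_src - 0.5), 3 * sqrt(0.25 / 1e4))
  frac <- vapply(1:50, function(s)
    mean(assign_stimulus(d, 1, 10, seed = s)$amplitudes < 0), 1.0)
  # pooled draws track the source fraction within 3 binomial SEs
  expect_lt(abs(mean(frac) - p_src), 3 * sqrt(0.25 / (50 * 100)))
})

test_that("V = 0 stimulation is bit-identical to no stimulation", {
  net <- tiny_population(I_exc = 50, g_noise = 0.05)
  stim <- assign_stimulus(as_dist(rnorm(100)), V = 0, f = 10, seed = 2,
                          n_per_region = 10)
  a <- simulate_network(net, NULL, duration = 2, seed = 3, transient_cut = 0.5)
  b <- simulate_network(net, stim, duration = 2, seed = 3, transient_cut = 0.5)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp, b$lfp)
})

test_that("simulation is deterministic in the seed", {
  net <- tiny_population(I_exc = 50, g_noise = 0.05)
  a <- simulate_network(net, NULL, duration = 2, seed = 7, transient_cut = 0.5)
  b <- simulate_network(net, NULL, duration = 2, seed = 7, transient_cut = 0.5)
  c <- simulate_network(net, NULL, duration = 2, seed = 8, transient_cut = 0.5)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp, b$lfp)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("LFP window honors duration, transient cut, and dt", {
  net <- tiny_population(I_exc = 50)
  sim <- simulate_network(net, NULL, duration = 1.5, dt = 0.1, seed = 1,
                          transient_cut = 0.5)
  expect_equal(ncol(sim$lfp), (1.5 - 0.5) * 1000 / 0.1)
  expect_error(simulate_network(net, NULL, duration = 1, transient_cut = 2),
               "duration")
})

test_that("a silent network emits no spikes and a zero LFP", {
  net <- tiny_population(I_exc = 0, I_inh = 0, g_noise = 0)
  sim <- simulate_network(net, NULL, duration = 1, seed = 1, transient_cut = 0)
  expect_equal(nrow(sim$spikes), 0)
  expect_true(all(sim$lfp == 0))
})

test_that("bias below rheobase stays silent; above it spikes with adaptation", {
  # analytic rheobase for the excitatory class:
  # I_rh = g_L (v_th - E_L) - g_L Delta_T + a (v_th - E_L)
  pe <- neuron_params("exc")
  I_rh <- pe$g_L * (pe$v_th - pe$E_L) - pe$g_L * pe$Delta_T +
    pe$a * (pe$v_th - pe$E_L)
  below <- tiny_population(n_exc = 1, n_inh = 0, I_exc = I_rh - 2, g_noise = 0)
  above <- tiny_population(n_exc = 1, n_inh = 0, I_exc = I_rh + 30, g_noise = 0)
  s0 <- simulate_network(below, NULL, duration = 3, seed = 1, transient_cut = 0)
  s1 <- simulate_network(above, NULL, duration = 3, seed = 1, transient_cut = 0)
  expect_equal(nrow(s0$spikes), 0)
  expect_gt(nrow(s1$spikes), 2)
  isi <- diff(s1$spikes$time_ms)
  # spike-triggered adaptation (b > 0): the first interval, before w has
  # accumulated, is the shortest
  expect_gt(length(isi), 2)
  expect_gt(isi[2], isi[1])
  expect_true(all(isi[-1] > isi[1]))
})

test_that("refractory period separates spikes by at least t_ref", {
  net <- tiny_population(n_exc = 5, n_inh = 0, I_exc = 800, g_noise = 0.2)
  sim <- simulate_network(net, NULL, duration = 2, seed = 1, transient_cut = 0)
  expect_gt(nrow(sim$spikes), 50)
  for (n in unique(sim$spikes$neuron)) {
    ts <- sim$spikes$time_ms[sim$spikes$neuron == n]
    expect_true(all(diff(ts) >= neuron_params("exc")$t_ref - 1e-9))
  }
})

test_that("one presynaptic spike produces an alpha-kernel conductance peaking at gbar", {
  # 1 E neuron driven to spike once; 1 I neuron as a passive recorder with a
  # huge leak clamping v at E_L. The region LFP is then the recorder's
  # synaptic current gbar * k(t) * (E_L - E_AMPA), maximal at lag
  # tau_AMPA + delay after the presynaptic spike.
  gbar <- 0.4
  exc <- neuron_params("exc", I = 50)   # slow regular spiking (b = 65)
  inh <- neuron_params("inh", I = 0, g_L = 200, C = 59)
  net <- build_population(exc, inh, synapse_params(g_AMPA = gbar, g_GABA = 1,
                                                   g_noise = 0),
                          n_exc = 1L, n_inh = 1L)
  sim <- simulate_network(net, NULL, duration = 1, dt = 0.1, seed = 1,
                          transient_cut = 0)
  expect_gt(nrow(sim$spikes), 0)
  t_sp <- sim$spikes$time_ms[1]
  t_next <- if (nrow(sim$spikes) > 1) sim$spikes$time_ms[2] else Inf
  expect_gt(t_next - t_sp, 15)   # adaptation keeps the next spike far away
  lfp <- compute_lfp(sim, 1)
  t_grid <- (seq_along(lfp) - 1) * 0.1
  win <- which(t_grid > t_sp & t_grid < t_sp + 15)
  i_peak <- win[which.max(abs(lfp[win]))]
  syn <- synapse_params()
  expect_equal(t_grid[i_peak] - t_sp, syn$tau_AMPA + 1.0, tolerance = 0.1001)
  # peak current = gbar * (v - E_AMPA) with v clamped near E_L = -62 mV
  expect_equal(max(abs(lfp[win])), gbar * 62, tolerance = gbar * 62 * 0.02)
})

test_that("two identical uncoupled regions with deterministic drive match exactly", {
  cn <- make_connectome(2, density = 1, seed = 1)
  net <- build_network(cn, omega = 0,
                       exc_params = neuron_params("exc", I = 50),
                       inh_params = neuron_params("inh", I = 0),
                       syn = synapse_params(g_noise = 0),
                       n_exc = 8L, n_inh = 2L)
  sim <- simulate_network(net, NULL, duration = 2, seed = 1, transient_cut = 0)
  expect_identical(compute_lfp(sim, 1), compute_lfp(sim, 2))
  expect_error(compute_lfp(sim, 3), "unknown region")
})

test_that("halving dt moves the baseline spectral peak by less than 2%", {
  net <- build_population()
  f_coarse <- vapply(1:2, function(s) {
    sim <- simulate_network(net, NULL, duration = 8, dt = 0.1, seed = s,
                            transient_cut = 2)
    welch_psd(compute_lfp(sim, 1), 0.1)$peak_freq
  }, 1.0)
  f_fine <- vapply(1:2, function(s) {
    sim <- simulate_network(net, NULL, duration = 8, dt = 0.05, seed = s,
                            transient_cut = 2)
    welch_psd(compute_lfp(sim, 1), 0.05)$peak_freq
  }, 1.0)
  expect_lt(abs(mean(f_fine) - mean(f_coarse)) / mean(f_coarse), 0.02)
})

test_that("the exponential term is clamped under extreme drive", {
  net <- tiny_population(n_exc = 4, n_inh = 1, I_exc = 0, g_noise = 0)
  stim <- assign_stimulus(as_dist(rep(1, 10)), V = 50000, f = 100, seed = 1,
                          n_per_region = 5)
  expect_no_error({
    sim <- simulate_network(net, stim, duration = 1, seed = 1, transient_cut = 0)
  })
  expect_true(all(is.finite(sim$lfp)))
  expect_true(all(diff(sim$spikes$time_ms[sim$spikes$neuron == 1]) >= 2 - 1e-9))
})

test_that("simulation results round-trip through the text archive", {
  net <- tiny_population(I_exc = 50, g_noise = 0.05)
  sim <- simulate_network(net, NULL, duration = 1, seed = 2, transient_cut = 0.2)
  stem <- tempfile()
  write_sim_result(sim, stem)
  back <- read_sim_result(stem)
  expect_equal(back$lfp, sim$lfp, tolerance = 1e-12)
  expect_equal(back$spikes, sim$spikes, tolerance = 1e-12)
  expect_equal(back$dt, sim$dt)
  expect_equal(back$transient_cut, sim$transient_cut)
})
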