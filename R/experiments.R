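#' Natural oscillation frequency of a model's baseline activity
#'
#' Runs unstimulated simulations and returns the mean LFP spectral peak of
#' the first region, the node's endogenous rhythm used to anchor sweeps and
#' stimulation protocols.
#'
#' @param model a `tacs_network`.
#' @param duration,dt,transient_cut simulation protocol (s, ms, s).
#' @param seeds integer vector of trial seeds.
#' @param region region index.
#' @return Mean peak frequency (Hz).
#' @export
natural_frequency <- function(model, duration = 12, dt = 0.1,
                              transient_cut = 4, seeds = 1:3, region = 1L) {
  peaks <- vapply(seeds, function(s) {
    sim <- simulate_network(model, NULL, duration = duration, dt = dt,
                            seed = s, transient_cut = transient_cut)
    welch_psd(compute_lfp(sim, region), dt)$peak_freq
  }, 1.0)
  mean(peaks)
}

#' Single-node entrainment sweep
#'
#' Simulates one stimulated region over a grid of stimulation frequency and
#' intensity, the Arnold-tongue map. Amplitudes are drawn from `dist` and
#' rescaled per cell so that the maximum injected amplitude equals the
#' cell's intensity in pA (i.e. V = intensity / max|A|); intensity 0
#' reproduces baseline exactly. Each cell records the LFP peak frequency,
#' its ratio to the stimulation frequency, and power at both frequencies.
#'
#' @param dist a `tacs_dist` (or numeric sample vector).
#' @param freqs stimulation frequencies (Hz, canonically within 4-18).
#' @param intensities peak injected currents (pA, canonically within
#'   0-200).
#' @param reps repetitions per cell (>= 1).
#' @param seed base seed; each (cell, rep) derives its own.
#' @param model single-region `tacs_network` (default
#'   [build_population()]).
#' @param duration,dt,transient_cut simulation protocol.
#' @return A `tacs_sweep` data.frame with columns `freq`, `intensity`,
#'   `rep`, `peak_freq`, `ratio`, `power_peak`, `power_stim` (one row per
#'   repetition). The attribute `"pooled"` holds one row per grid cell
#'   with `peak_freq` and `ratio` measured on the repetition-averaged
#'   Welch spectrum — the robust read-out when single repetitions are
#'   short, since spectral noise can tip the argmax onto a harmonic of a
#'   locked rhythm ([sweep_cells()] retrieves it).
#' @export
single_node_sweep <- function(dist, freqs, intensities, reps = 3, seed = 1,
                              model = build_population(), duration = 50,
                              dt = 0.1, transient_cut = 4) {
  if (!inherits(dist, "tacs_dist")) dist <- as_dist(dist)
  if (reps < 1) stop("reps must be >= 1")
  amax <- max(abs(dist$samples))
  if (amax == 0) stop("distribution has no nonzero amplitudes")
  grid <- expand.grid(rep = seq_len(reps), intensity = intensities,
                      freq = freqs)
  specs <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    # the seed depends on (intensity, rep) but not frequency, so the
    # intensity-0 row reproduces one baseline realization per rep across
    # all stimulation frequencies
    cell_seed <- seed * 10000L + match(g$intensity, intensities) * 100L + g$rep
    stim <- if (g$intensity > 0)
      assign_stimulus(dist, V = g$intensity / amax, f = g$freq,
                      seed = cell_seed,
                      n_per_region = model$n_exc + model$n_inh)
    else NULL
    sim <- simulate_network(model, stim, duration = duration, dt = dt,
                            seed = cell_seed, transient_cut = transient_cut)
    spec <- welch_psd(compute_lfp(sim, 1L), dt)
    specs[[i]] <<- spec
    p_stim <- spec$power[which.min(abs(spec$freq - g$freq))]
    data.frame(freq = g$freq, intensity = g$intensity, rep = g$rep,
               peak_freq = spec$peak_freq, ratio = spec$peak_freq / g$freq,
               power_peak = max(spec$power[spec$freq >= 2]),
               power_stim = p_stim)
  })
  out <- do.call(rbind, rows)

  # per-cell peaks of the repetition-averaged spectrum
  cell_id <- paste(grid$freq, grid$intensity)
  pooled <- lapply(unique(cell_id), function(id) {
    idx <- which(cell_id == id)
    avg <- specs[[idx[1]]]
    if (length(idx) > 1)
      avg$power <- rowMeans(vapply(specs[idx], `[[`, avg$power, "power"))
    pb <- avg$freq >= 2
    pk <- avg$freq[pb][which.max(avg$power[pb])]
    data.frame(freq = grid$freq[idx[1]], intensity = grid$intensity[idx[1]],
               peak_freq = pk, ratio = pk / grid$freq[idx[1]])
  })
  attr(out, "pooled") <- do.call(rbind, pooled)
  class(out) <- c("tacs_sweep", class(out))
  out
}

#' Per-cell results of a sweep from the repetition-averaged spectra
#'
#' @param sweep a `tacs_sweep` from [single_node_sweep()].
#' @return data.frame with one row per (freq, intensity) cell: `peak_freq`
#'   and `ratio` of the repetition-averaged Welch spectrum.
#' @export
sweep_cells <- function(sweep) {
  p <- attr(sweep, "pooled")
  if (is.null(p)) stop("sweep carries no pooled spectra")
  p
}

#' Classify a peak-to-stimulation frequency ratio into a locking regime
#'
#' Deterministic boundaries around the named synchronization states:
#' 1:1 entrainment, 2:1 (frequency doubling), an intermediate "faster"
#' regime (~50% above the stimulation frequency), and a "slower" regime
#' below it; everything else is unlocked.
#'
#' @param ratio LFP-peak-to-stimulation frequency ratio (> 0).
#' @param tol classification tolerance (default 0.05).
#' @return One of `"one-to-one"`, `"two-to-one"`, `"faster"`, `"slower"`,
#'   `"unlocked"`.
#' @export
#' @examples
#' classify_sync_state(2.01)  # "two-to-one"
classify_sync_state <- function(ratio, tol = 0.05) {
  if (any(ratio <= 0)) stop("ratio must be > 0")
  vapply(ratio, function(r) {
    if (abs(r - 1) <= tol) "one-to-one"
    else if (abs(r - 2) <= 2 * tol) "two-to-one"
    else if (r > 1 + tol && r < 2 - 2 * tol) "faster"
    else if (r < 1 - tol) "slower"
    else "unlocked"
  }, character(1))
}

#' Percentage alpha-power rise between baseline and stimulated runs
#'
#' The trial-specific individual alpha frequency (IAF) is the median over
#' cluster regions of the baseline LFP spectral peaks in 8-12 Hz — one IAF
#' per trial, the same frequency the IAF-locked stimulation protocol
#' targets. Power is integrated over IAF +/- 0.5 Hz per cluster region in
#' both runs and averaged over the cluster; the rise is
#' 100 * (P_stim - P_base) / P_base.
#'
#' @param baseline,stim `tacs_sim` results from the same model.
#' @param cluster region indices defining the cluster (default: all).
#' @param halfwidth band half width around the IAF (Hz, default 0.5).
#' @param iaf override the trial IAF (Hz); default: measured from the
#'   baseline run.
#' @return Percent change (scalar).
#' @export
alpha_rise <- function(baseline, stim, cluster = NULL, halfwidth = 0.5,
                       iaf = NULL) {
  stopifnot(inherits(baseline, "tacs_sim"), inherits(stim, "tacs_sim"))
  if (is.null(cluster)) cluster <- seq_len(nrow(baseline$lfp))
  specs_b <- lapply(cluster, function(k)
    welch_psd(compute_lfp(baseline, k), baseline$dt, peak_band = c(8, 12)))
  if (is.null(iaf))
    iaf <- stats::median(vapply(specs_b, `[[`, 1.0, "peak_freq"))
  p_base <- vapply(specs_b, band_power, 1.0, center = iaf,
                   halfwidth = halfwidth)
  p_stim <- vapply(cluster, function(k)
    band_power(welch_psd(compute_lfp(stim, k), stim$dt), iaf, halfwidth),
    1.0)
  P_base <- mean(p_base); P_stim <- mean(p_stim)
  if (P_base == 0) stop("degenerate baseline: zero alpha power")
  100 * (P_stim - P_base) / P_base
}

#' Calibrate the stimulation-intensity scaling constant
#'
#' Grid search over the global scaling constant V: for every cohort member
#' and repetition, a baseline run fixes the trial-specific IAF (the
#' stimulation frequency) and baseline alpha power; stimulated runs with
#' per-neuron amplitudes drawn from the member's per-region
#' normal-component distributions measure the cluster alpha rise. V* is
#' the grid value whose group-mean rise is closest to `target_rise`.
#'
#' @param cohort list of subjects, each a list with `model`
#'   (`tacs_network`), `dists` (list of `tacs_dist`, one per region) and
#'   optionally `cluster` (region indices, default all).
#' @param target_rise target group-mean alpha rise (percent).
#' @param V_grid candidate scaling constants (pA per field unit).
#' @param reps repetitions per subject and intensity.
#' @param seed base seed.
#' @param duration,dt,transient_cut simulation protocol.
#' @param baseline_duration length of the baseline runs (s; default
#'   `duration`). A longer baseline sharpens the IAF estimate and the
#'   normalizing band power, which stabilizes the rise estimates at no
#'   cost to the stimulated runs.
#' @return A `tacs_calibration`: list with `V_star`, `achieved_rise`
#'   (group mean at V*), `group_mean` (per V), and `rises` (data.frame
#'   subject/V/rep/rise).
#' @export
calibrate_intensity <- function(cohort, target_rise = 8.02, V_grid,
                                reps = 1, seed = 1, duration = 12, dt = 0.1,
                                transient_cut = 4,
                                baseline_duration = duration) {
  stopifnot(length(cohort) >= 1, length(V_grid) >= 1)
  rows <- list()
  for (s in seq_along(cohort)) {
    subj <- cohort[[s]]
    cluster <- if (is.null(subj$cluster)) seq_len(subj$model$n_regions)
               else subj$cluster
    n_per <- subj$model$n_exc + subj$model$n_inh
    for (r in seq_len(reps)) {
      trial_seed <- seed * 10000L + s * 100L + r
      base <- simulate_network(subj$model, NULL, duration = baseline_duration,
                               dt = dt, seed = trial_seed,
                               transient_cut = transient_cut)
      # trial-specific IAF of the cluster sets the stimulation frequency
      iafs <- vapply(cluster, function(k)
        welch_psd(compute_lfp(base, k), dt, peak_band = c(8, 12))$peak_freq,
        1.0)
      f_stim <- stats::median(iafs)
      for (V in V_grid) {
        rise <- if (V == 0) 0 else {
          stim <- assign_stimulus(subj$dists, V = V, f = f_stim,
                                  seed = trial_seed, n_per_region = n_per)
          sim <- simulate_network(subj$model, stim, duration = duration,
                                  dt = dt, seed = trial_seed,
                                  transient_cut = transient_cut)
          alpha_rise(base, sim, cluster = cluster)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, V = V, rep = r, rise = rise)
      }
    }
  }
  rises <- do.call(rbind, rows)
  gm <- stats::aggregate(rise ~ V, rises, mean)
  best <- select_intensity(gm, target_rise)
  structure(list(V_star = gm$V[best], achieved_rise = gm$rise[best],
                 group_mean = gm, rises = rises,
                 target_rise = target_rise),
            class = "tacs_calibration")
}

#' Pick the calibrated intensity from a response curve
#'
#' Index of the grid value whose group-mean rise is closest to the target
#' (ties resolved toward the smaller intensity).
#'
#' @param group_mean data.frame with columns `V` and `rise`.
#' @param target_rise target percent rise.
#' @return Integer row index of the selected intensity.
#' @export
select_intensity <- function(group_mean, target_rise) {
  stopifnot(all(c("V", "rise") %in% names(group_mean)))
  ord <- order(group_mean$V)
  gm <- group_mean[ord, ]
  best <- which.min(abs(gm$rise - target_rise))
  ord[best]
}

#' @export
print.tacs_calibration <- function(x, ...) {
  cat(sprintf("tacs_calibration: V* = %g, achieved group-mean rise = %.2f%% (target %.2f%%)\n",
              x$V_star, x$achieved_rise, x$target_rise))
  invisible(x)
}
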