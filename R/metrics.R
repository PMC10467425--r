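#' Welch power spectral density
#'
#' Welch's method with 2 s Hann-tapered segments at 50% overlap, evaluated
#' on a 0-45 Hz grid with resolution <= 0.25 Hz (segments are zero-padded
#' as needed). `power` is the one-sided density in input-units^2/Hz, whose
#' integral over the grid matches the time-domain variance (Parseval);
#' `power_norm` is the same density normalized by total 2-45 Hz power, the
#' convention used when comparing spectra across trials.
#'
#' @param series numeric time series (>= 2 s of samples).
#' @param dt sample step (ms).
#' @param seg_s segment length (s, default 2).
#' @param fmax upper frequency of the grid (Hz, default 45).
#' @param df target grid resolution (Hz, default 0.25).
#' @param peak_band band searched for the spectral peak (Hz,
#'   default c(2, fmax), excluding the DC neighborhood).
#' @return A `tacs_psd`: list with `freq`, `power`, `power_norm`,
#'   `peak_freq`, `df`.
#' @export
#' @examples
#' t <- seq(0, 8, by = 1e-4)[-1]
#' p <- welch_psd(sin(2 * pi * 10 * t), dt = 0.1)
#' p$peak_freq
welch_psd <- function(series, dt, seg_s = 2, fmax = 45, df = 0.25,
                      peak_band = NULL) {
  x <- as.numeric(series)
  fs <- 1000 / dt                      # Hz
  seg_len <- round(seg_s * fs)
  if (length(x) < seg_len) stop("insufficient data: need >= ", seg_s, " s")
  if (is.null(peak_band)) peak_band <- c(2, fmax)

  nfft <- max(seg_len, ceiling(fs / df))
  step <- seg_len %/% 2
  starts <- seq(1, length(x) - seg_len + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  U <- sum(win^2)

  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(c(seg, numeric(nfft - seg_len)))
    pxx <- Mod(X)^2 / (U * fs)
    acc <- if (is.null(acc)) pxx else acc + pxx
  }
  pxx <- acc / length(starts)
  freq <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freq <= fmax
  freq <- freq[keep]
  pxx <- pxx[keep]
  pxx[-1] <- 2 * pxx[-1]               # one-sided

  in_band <- freq >= 2 & freq <= fmax
  tot <- trapz_(freq[in_band], pxx[in_band])
  pb <- freq >= peak_band[1] & freq <= peak_band[2]
  peak <- freq[pb][which.max(pxx[pb])]
  structure(list(freq = freq, power = pxx,
                 power_norm = if (tot > 0) pxx / tot else pxx,
                 peak_freq = peak, df = freq[2] - freq[1]),
            class = "tacs_psd")
}

trapz_ <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Band power from a spectral summary
#'
#' Trapezoidal integral of the power density over
#' [center - halfwidth, center + halfwidth].
#'
#' @param spec a `tacs_psd`.
#' @param center band center (Hz).
#' @param halfwidth half bandwidth (Hz).
#' @param normalized integrate the normalized density instead of the raw
#'   one (default FALSE).
#' @return Scalar band power.
#' @export
band_power <- function(spec, center, halfwidth, normalized = FALSE) {
  stopifnot(inherits(spec, "tacs_psd"))
  lo <- center - halfwidth; hi <- center + halfwidth
  if (hi < min(spec$freq) || lo > max(spec$freq))
    stop("band outside the frequency grid")
  keep <- spec$freq >= lo & spec$freq <= hi
  if (sum(keep) < 2) return(0)
  y <- if (normalized) spec$power_norm else spec$power
  trapz_(spec$freq[keep], y[keep])
}

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Decimate to ~250 Hz (multi-stage FIR) then zero-phase 4th-order
# Butterworth band-pass. Returns list(x, fs).
bandpass_ <- function(x, dt, band) {
  fs <- 1000 / dt
  q <- max(1L, floor(fs / 250))
  while (q > 1) {
    qi <- min(q, 10L)
    x <- signal::decimate(x, qi, ftype = "fir")
    fs <- fs / qi
    q <- q %/% qi
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  list(x = signal::filtfilt(bf, x - mean(x)), fs = fs)
}

#' Phase-locking value between two time series
#'
#' Band-passes both series (zero-phase 4th-order Butterworth, default
#' 8-12 Hz, after decimation to ~250 Hz), extracts instantaneous phases via
#' the analytic signal, trims 1 s from each edge, and returns
#' PLV = |mean(exp(i * (phi_a - phi_b)))| over time samples. 1 means a
#' constant phase relation, values near 0 mean no locking.
#'
#' @param series_a,series_b equal-length numeric series.
#' @param band band-pass edges (Hz, default c(8, 12)).
#' @param dt sample step (ms).
#' @return PLV in [0, 1].
#' @export
plv <- function(series_a, series_b, band = c(8, 12), dt = 0.1) {
  if (length(series_a) != length(series_b))
    stop("series must have equal lengths")
  a <- bandpass_(as.numeric(series_a), dt, band)
  b <- bandpass_(as.numeric(series_b), dt, band)
  trim <- round(a$fs)                   # 1 s edge trim
  n <- length(a$x)
  if (n <= 2 * trim + 8) stop("series too short for PLV")
  idx <- (trim + 1):(n - trim)
  pa <- Arg(analytic_signal(a$x))[idx]
  pb <- Arg(analytic_signal(b$x))[idx]
  Mod(mean(exp(1i * (pa - pb))))
}

#' Simulated functional connectivity (PLV matrix)
#'
#' Pairwise phase-locking values between all region LFPs of a simulation.
#'
#' @param result a `tacs_sim` with >= 2 regions.
#' @param band band-pass edges (Hz).
#' @return Symmetric region x region matrix with unit diagonal.
#' @export
fc_matrix <- function(result, band = c(8, 12)) {
  stopifnot(inherits(result, "tacs_sim"))
  K <- nrow(result$lfp)
  if (K < 2) stop("need >= 2 regions")
  M <- diag(1, K)
  for (i in 1:(K - 1))
    for (j in (i + 1):K)
      M[i, j] <- M[j, i] <- plv(result$lfp[i, ], result$lfp[j, ],
                                band = band, dt = result$dt)
  M
}

#' Correlation between simulated and target connectivity
#'
#' Pearson correlation between the vectorized strictly-upper-triangular
#' entries of two region x region matrices, the standard goodness-of-fit
#' when tuning the network coupling.
#'
#' @param sim_fc,target_fc equal-shape square matrices.
#' @return Pearson r.
#' @export
fc_fit <- function(sim_fc, target_fc) {
  if (inherits(target_fc, "tacs_fc")) target_fc <- target_fc$plv
  if (!all(dim(sim_fc) == dim(target_fc))) stop("shape mismatch")
  ut <- upper.tri(sim_fc)
  stats::cor(sim_fc[ut], target_fc[ut])
}

#' Select the network working point from a coupling scan
#'
#' Among candidate couplings, keeps those whose mean PLV stays below a
#' plausibility ceiling (hyper-synchronized states are discarded) and whose
#' median regional peak frequency lies in the alpha band, then returns the
#' candidate maximizing the FC-fit correlation r.
#'
#' @param candidates a data.frame with columns `omega`, `r`, `mean_plv`,
#'   and either `median_peak` or a list-column `peak_freqs`.
#' @param plv_ceiling maximum admissible mean PLV (default 0.8).
#' @param alpha_band admissible band for the median peak frequency
#'   (default c(8, 12) Hz).
#' @return A `tacs_working_point`: one-row list with `omega`, `r`,
#'   `mean_plv`, `median_peak`.
#' @export
select_working_point <- function(candidates, plv_ceiling = 0.8,
                                 alpha_band = c(8, 12)) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1)
  med <- if ("median_peak" %in% names(candidates)) candidates$median_peak
         else vapply(candidates$peak_freqs, stats::median, 1.0)
  ok <- candidates$mean_plv <= plv_ceiling &
    med >= alpha_band[1] & med <= alpha_band[2]
  if (!any(ok)) stop("no feasible working point")
  feas <- which(ok)
  best <- feas[which.max(candidates$r[feas])]
  structure(list(omega = candidates$omega[best], r = candidates$r[best],
                 mean_plv = candidates$mean_plv[best],
                 median_peak = med[best]),
            class = "tacs_working_point")
}
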