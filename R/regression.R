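#' Build a standardized regression table of alpha-rise predictors
#'
#' Assembles the per-(subject, region) table used to model stimulation
#' efficacy: the response is the percent alpha-power change, the seven
#' candidate predictors are the squared mean of the normal-component
#' distribution, its skewness, kurtosis and mode count, the base-2
#' logarithm of the structural node strength, the region's baseline mean
#' PLV, and the stimulation-minus-baseline frequency mismatch. Predictors
#' are standardized (mean 0, unit variance) so coefficient magnitudes are
#' comparable.
#'
#' @param response numeric vector, percent alpha change per row.
#' @param predictors data.frame with one numeric column per predictor.
#' @return A `tacs_regtable` data.frame: `response` plus standardized
#'   predictor columns.
#' @export
make_regression_table <- function(response, predictors) {
  stopifnot(is.data.frame(predictors), nrow(predictors) == length(response))
  if (anyNA(response) || anyNA(predictors)) stop("missing cells not allowed")
  std <- as.data.frame(lapply(predictors, function(x) {
    s <- stats::sd(x)
    if (s == 0) stop("constant predictor cannot be standardized")
    (x - mean(x)) / s
  }))
  out <- cbind(data.frame(response = response), std)
  class(out) <- c("tacs_regtable", class(out))
  out
}

#' Seven canonical predictors from pipeline objects
#'
#' Convenience constructor computing the predictor columns from a list of
#' per-region distributions, a connectome, a baseline FC matrix, and the
#' stimulation/baseline frequencies.
#'
#' @param dists list of summarized `tacs_dist`, one per region.
#' @param connectome a `tacs_connectome`.
#' @param baseline_fc region x region baseline PLV matrix.
#' @param stim_freq stimulation frequency (Hz).
#' @param baseline_freqs per-region baseline peak frequencies (Hz).
#' @return data.frame with columns `sq_mean`, `skewness`, `kurtosis`,
#'   `n_modes`, `log2_strength`, `baseline_plv`, `freq_mismatch`.
#' @export
regression_predictors <- function(dists, connectome, baseline_fc, stim_freq,
                                  baseline_freqs) {
  K <- length(dists)
  stopifnot(nrow(connectome$weights) == K, nrow(baseline_fc) == K,
            length(baseline_freqs) == K)
  strength <- rowSums(connectome$weights)
  data.frame(
    sq_mean = vapply(dists, `[[`, 1.0, "squared_mean"),
    skewness = vapply(dists, `[[`, 1.0, "skewness"),
    kurtosis = vapply(dists, `[[`, 1.0, "kurtosis"),
    n_modes = vapply(dists, function(d) as.numeric(d$n_modes), 1.0),
    log2_strength = log2(pmax(strength, .Machine$double.eps)),
    baseline_plv = (rowSums(baseline_fc) - 1) / (K - 1),
    freq_mismatch = stim_freq - baseline_freqs)
}

#' Robust multiple linear regression of stimulation efficacy
#'
#' Huber-weighted iteratively reweighted least squares (tuning constant
#' 1.345, convergence 1e-8, at most 50 iterations) of the response on all
#' predictor columns. With `stepwise = TRUE`, backward elimination
#' iteratively drops the least-significant predictor with p > 0.05 and
#' refits. P-values are two-sided t-tests on the robust coefficient
#' estimates with n - p degrees of freedom.
#'
#' @param table a `tacs_regtable` (response + standardized predictors).
#' @param stepwise apply backward elimination (default TRUE).
#' @param alpha significance level for elimination (default 0.05).
#' @return A `tacs_mlr`: list with `coefficients` (data.frame term,
#'   estimate, se, t, p), `retained`, `dropped`, `n`, and the underlying
#'   fit object (`fit`, NULL for degenerate inputs).
#' @export
robust_mlr <- function(table, stepwise = TRUE, alpha = 0.05) {
  stopifnot(is.data.frame(table), "response" %in% names(table))
  preds <- setdiff(names(table), "response")
  if (nrow(table) < 3 * length(preds))
    stop("need at least 3 rows per predictor")
  y <- table$response

  if (stats::sd(y) == 0) {
    # constant response: nothing to explain
    coefs <- data.frame(term = preds, estimate = 0, se = 0, t = 0, p = 1)
    return(structure(list(coefficients = coefs, retained = character(0),
                          dropped = preds, n = nrow(table), fit = NULL),
                     class = "tacs_mlr"))
  }

  X <- as.matrix(table[preds])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- preds[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop("collinearity: rank-deficient design, offending column(s): ",
         paste(bad, collapse = ", "))
  }

  fit_once <- function(vars) {
    fml <- if (length(vars)) stats::reformulate(vars, response = "response")
           else response ~ 1
    fit <- MASS::rlm(fml, data = table, psi = MASS::psi.huber, k = 1.345,
                     maxit = 50, acc = 1e-8)
    sm <- summary(fit)$coefficients
    df <- nrow(table) - nrow(sm)
    list(fit = fit,
         coefs = data.frame(term = rownames(sm), estimate = sm[, 1],
                            se = sm[, 2], t = sm[, 3],
                            p = 2 * stats::pt(-abs(sm[, 3]), df),
                            row.names = NULL))
  }

  vars <- preds; dropped <- character(0)
  repeat {
    res <- fit_once(vars)
    co <- res$coefs[res$coefs$term != "(Intercept)", ]
    if (!stepwise || nrow(co) == 0) break
    worst <- which.max(co$p)
    if (co$p[worst] <= alpha) break
    dropped <- c(dropped, co$term[worst])
    vars <- setdiff(vars, co$term[worst])
    if (length(vars) == 0) { res <- fit_once(vars); break }
  }
  structure(list(coefficients = res$coefs,
                 retained = setdiff(res$coefs$term, c("(Intercept)", dropped)),
                 dropped = dropped, n = nrow(table), fit = res$fit),
            class = "tacs_mlr")
}

#' @export
print.tacs_mlr <- function(x, ...) {
  cat("Robust (Huber IRLS) regression, n =", x$n, "\n")
  print(x$coefficients, digits = 3)
  if (length(x$dropped)) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Robust regression restricted to power-lowering regions
#'
#' Refits [robust_mlr()] on the subset of rows whose response is negative,
#' to ask which predictors drive an actual power decrease rather than a
#' softened rise. Returns an explicit empty result when no row qualifies.
#'
#' @inheritParams robust_mlr
#' @return A `tacs_mlr`, or a `tacs_mlr` with zero-row coefficients when
#'   the subset is empty.
#' @export
lowered_subset_mlr <- function(table, stepwise = TRUE, alpha = 0.05) {
  stopifnot(is.data.frame(table), "response" %in% names(table))
  sub <- table[table$response < 0, , drop = FALSE]
  if (nrow(sub) == 0) {
    coefs <- data.frame(term = character(0), estimate = numeric(0),
                        se = numeric(0), t = numeric(0), p = numeric(0))
    return(structure(list(coefficients = coefs, retained = character(0),
                          dropped = character(0), n = 0L, fit = NULL),
                     class = "tacs_mlr"))
  }
  class(sub) <- class(table)
  robust_mlr(sub, stepwise = stepwise, alpha = alpha)
}

#' Paired Wilcoxon comparisons with Holm correction and effect sizes
#'
#' One-sided Wilcoxon signed-rank test (stimulated > baseline) per subject
#' over paired repetitions, with the family of per-subject p-values
#' corrected by Holm's step-down procedure. W is the rank sum of the
#' unfavorable (negative) differences, so W = 0 when every repetition
#' increased. Effect sizes: rank-biserial correlation
#' RBC = (R+ - R-) / (R+ + R-), and the common-language effect size CLES =
#' fraction of all (stimulated, baseline) cross-pairs favoring stimulation
#' (ties count 1/2).
#'
#' @param per_subject_pairs list, one element per subject, each a list with
#'   numeric vectors `base` and `stim` of equal length (>= 5 pairs).
#' @param family_alpha family-wise level for the Holm flags (default 0.05).
#' @return A `tacs_wilcoxon` data.frame: subject, W, p, p_holm,
#'   significant, rbc, cles. Subjects with all-zero differences get NA
#'   statistics (undefined test) and are excluded from the correction.
#' @export
wilcoxon_holm <- function(per_subject_pairs, family_alpha = 0.05) {
  stopifnot(length(per_subject_pairs) >= 1)
  rows <- lapply(seq_along(per_subject_pairs), function(s) {
    pr <- per_subject_pairs[[s]]
    stopifnot(length(pr$base) == length(pr$stim), length(pr$base) >= 5)
    d <- pr$stim - pr$base
    nz <- d[d != 0]
    cles <- mean(outer(pr$stim, pr$base, ">") +
                   0.5 * outer(pr$stim, pr$base, "=="))
    if (length(nz) == 0)
      return(data.frame(subject = s, W = NA_real_, p = NA_real_, rbc = NA_real_,
                        cles = cles))
    rk <- rank(abs(nz))
    R_plus <- sum(rk[nz > 0]); R_minus <- sum(rk[nz < 0])
    p <- suppressWarnings(stats::wilcox.test(pr$stim, pr$base, paired = TRUE,
                                             alternative = "greater"))$p.value
    data.frame(subject = s, W = R_minus, p = p,
               rbc = (R_plus - R_minus) / (R_plus + R_minus), cles = cles)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  ok <- !is.na(out$p)
  out$p_holm[ok] <- stats::p.adjust(out$p[ok], method = "holm")
  out$significant <- !is.na(out$p_holm) & out$p_holm <= family_alpha
  out <- out[c("subject", "W", "p", "p_holm", "significant", "rbc", "cles")]
  class(out) <- c("tacs_wilcoxon", class(out))
  out
}
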