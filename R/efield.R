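#' Project a field map onto surface normals
#'
#' Computes the normal component of the electric field for every triangle,
#' the scalar product of the field vector with the unit normal oriented
#' toward white matter:  E_perp = E . n = |E| cos(theta).  Fields aligned
#' with the orthodromic direction (dendritic tuft toward axon, i.e. into the
#' white matter) give positive values; antidromic alignment gives negative
#' values.
#'
#' @param field a `tacs_field` (or T x 3 matrix) of field vectors, V/m.
#' @param mesh a `tacs_mesh` with the same number of triangles.
#' @return Numeric vector of per-triangle normal components (V/m).
#' @export
#' @examples
#' m <- make_gyrified_mesh(0, 0, 10, 4, seed = 1)
#' f <- make_uniform_field(m, c(0, 0, -1), 0.2)
#' head(project_normal(f, m))  # flat sheet: all 0.2
project_normal <- function(field, mesh) {
  stopifnot(inherits(mesh, "tacs_mesh"))
  E <- unclass(field)
  if (!is.matrix(E) || ncol(E) != 3) stop("field must be a T x 3 matrix")
  if (nrow(E) != nrow(mesh$triangles))
    stop("field and mesh have different triangle counts")
  if (!all(is.finite(E))) stop("field contains non-finite components")
  rowSums(E * mesh$normals)
}

#' Group per-triangle normal components by parcel
#'
#' Pools the projected components into one distribution per region label,
#' the per-region sample sets that drive stimulation and serve as regression
#' predictors.
#'
#' @param components numeric vector aligned with the mesh triangles.
#' @param mesh the `tacs_mesh` the components came from.
#' @param summarize compute distribution summaries on each group
#'   (default TRUE; requires >= 3 samples per region).
#' @return A list of `tacs_dist` objects (class `tacs_dist_list`), one per
#'   distinct region label, each with fields `region`, `samples`, and (if
#'   summarized) `mean`, `squared_mean`, `skewness`, `kurtosis`, `n_modes`.
#' @export
group_by_region <- function(components, mesh, summarize = TRUE) {
  stopifnot(inherits(mesh, "tacs_mesh"))
  if (length(components) != nrow(mesh$triangles))
    stop("components not aligned with mesh triangles")
  sets <- split(components, mesh$region)
  out <- lapply(names(sets), function(r) {
    d <- new_dist(as.integer(r), sets[[r]])
    if (summarize && length(sets[[r]]) >= 3) d <- summarize_distribution(d)
    d
  })
  structure(out, class = "tacs_dist_list")
}

new_dist <- function(region, samples) {
  structure(list(region = region, samples = as.numeric(samples),
                 mean = NA_real_, squared_mean = NA_real_,
                 skewness = NA_real_, kurtosis = NA_real_,
                 n_modes = NA_integer_),
            class = "tacs_dist")
}

#' Normal-component distribution from a raw sample set
#'
#' Wraps a numeric sample vector (for example one of the prototypical
#' distributions from [make_theoretical_distribution()]) as a
#' `tacs_dist` with summaries filled in.
#'
#' @param samples numeric vector (>= 3 values for summaries).
#' @param region optional region id.
#' @return A `tacs_dist`.
#' @export
as_dist <- function(samples, region = 1L) {
  d <- new_dist(region, samples)
  if (length(samples) >= 3) d <- summarize_distribution(d) else
    d$n_modes <- if (length(samples) >= 1) 1L else NA_integer_
  d
}

#' Summary statistics of a normal-component distribution
#'
#' Fills in the five summaries used as predictors of stimulation efficacy:
#' mean, squared mean (mean^2; the stimulation effect is expected to be
#' symmetric in the sign of the mean), sample skewness, sample excess
#' kurtosis (normal = 0), and the number of modes of a kernel-density
#' estimate (see [count_modes()]).
#'
#' @param dist a `tacs_dist` with at least 3 samples.
#' @return The `tacs_dist` with summaries filled in.
#' @export
summarize_distribution <- function(dist) {
  stopifnot(inherits(dist, "tacs_dist"))
  x <- dist$samples
  if (length(x) < 3) stop("insufficient data: need >= 3 samples")
  m <- mean(x)
  xc <- x - m
  m2 <- mean(xc^2)
  dist$mean <- m
  dist$squared_mean <- m^2
  if (m2 == 0) {
    dist$skewness <- 0
    dist$kurtosis <- 0
  } else {
    dist$skewness <- mean(xc^3) / m2^1.5
    dist$kurtosis <- mean(xc^4) / m2^2 - 3
  }
  dist$n_modes <- count_modes(x)
  dist
}

#' Count modes of a sample by kernel-density peaks
#'
#' Number of local maxima of a Gaussian kernel-density estimate with
#' Silverman's rule-of-thumb bandwidth, evaluated on a 512-point grid
#' spanning the sample range extended by 3 bandwidths. A local maximum
#' counts as a mode only if its density exceeds 5% of the global maximum,
#' which suppresses spurious shoulder peaks.
#'
#' @param samples numeric vector (>= 3 values).
#' @param prominence minimum density relative to the global maximum
#'   (default 0.05).
#' @return Integer mode count (>= 1 for any non-degenerate sample).
#' @export
#' @examples
#' count_modes(rnorm(1000))                          # 1
#' count_modes(c(rnorm(500, -0.1, 0.03), rnorm(500, 0.1, 0.03)))  # 2
count_modes <- function(samples, prominence = 0.05) {
  x <- as.numeric(samples)
  if (length(x) < 3) stop("insufficient data: need >= 3 samples")
  if (stats::sd(x) == 0) return(1L)   # point mass
  bw <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = 512,
                      from = min(x) - 3 * bw, to = max(x) + 3 * bw)
  y <- d$y
  floor_y <- prominence * max(y)
  n <- length(y)
  is_max <- y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
    y[2:(n - 1)] > floor_y
  max(1L, sum(is_max))
}

#' Pool several distributions into one
#'
#' Concatenates the sample sets of multiple regions (or multiple subjects'
#' versions of the same region) into a single distribution, as used when
#' displaying cohort-accumulated histograms. Per-mesh distributions remain
#' the default unit of analysis; pooling is an explicit choice.
#'
#' @param dists a list of `tacs_dist` objects.
#' @param region region id for the pooled distribution.
#' @return A summarized `tacs_dist`.
#' @export
pool_distributions <- function(dists, region = NA_integer_) {
  stopifnot(length(dists) >= 1, all(vapply(dists, inherits, TRUE, "tacs_dist")))
  as_dist(unlist(lapply(dists, `[[`, "samples")), region = region)
}

#' @export
print.tacs_dist <- function(x, ...) {
  cat(sprintf("tacs_dist (region %s): n = %d, mean = %.4g, skew = %.3g, exkurt = %.3g, modes = %s\n",
              x$region, length(x$samples), x$mean, x$skewness, x$kurtosis,
              x$n_modes))
  invisible(x)
}
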