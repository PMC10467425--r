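#' Write / read a surface mesh as ASCII OFF
#'
#' Standard OFF with per-face region labels stored as a trailing integer on
#' each face row (read back into `region`); normals are recomputed on read
#' with the white-matter-side orientation convention of
#' [make_gyrified_mesh()].
#'
#' @param mesh a `tacs_mesh`.
#' @param path output file.
#' @return `write_mesh_off()`: the path, invisibly. `read_mesh_off()`: a
#'   `tacs_mesh`.
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "tacs_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste("3", mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L, mesh$region), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  stopifnot(trimws(lines[1]) == "OFF")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vertices <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                          quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)], collapse = "\n"),
                    quiet = TRUE), ncol = 5, byrow = TRUE)
  tri <- matrix(as.integer(fl[, 2:4] + 1L), ncol = 3)
  region <- as.integer(fl[, 5])
  e1 <- vertices[tri[, 2], ] - vertices[tri[, 1], ]
  e2 <- vertices[tri[, 3], ] - vertices[tri[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  flip <- nrm[, 3] > 0
  nrm[flip, ] <- -nrm[flip, ]
  centroids <- (vertices[tri[, 1], ] + vertices[tri[, 2], ] + vertices[tri[, 3], ]) / 3
  structure(list(vertices = vertices, triangles = tri, normals = nrm,
                 region = region, centroids = centroids),
            class = "tacs_mesh")
}

#' Write / read a connectome as CSV
#'
#' Two CSV files (`<stem>_weights.csv`, `<stem>_lengths.csv`) with a header
#' row of region ids.
#'
#' @param connectome a `tacs_connectome`.
#' @param stem path stem (without suffix).
#' @return `write_connectome_csv()`: the stem, invisibly.
#'   `read_connectome_csv()`: a `tacs_connectome`.
#' @export
write_connectome_csv <- function(connectome, stem) {
  stopifnot(inherits(connectome, "tacs_connectome"))
  w <- connectome$weights; l <- connectome$lengths
  colnames(w) <- colnames(l) <- connectome$region_ids
  utils::write.csv(w, paste0(stem, "_weights.csv"), row.names = FALSE)
  utils::write.csv(l, paste0(stem, "_lengths.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(stem) {
  w <- as.matrix(utils::read.csv(paste0(stem, "_weights.csv"), check.names = FALSE))
  l <- as.matrix(utils::read.csv(paste0(stem, "_lengths.csv"), check.names = FALSE))
  dimnames(w) <- dimnames(l) <- NULL
  structure(list(region_ids = seq_len(nrow(w)), weights = w, lengths = l),
            class = "tacs_connectome")
}

#' Write per-region distributions as CSV with a JSON summary sidecar
#'
#' Long-format CSV (`region`, `sample`) plus `<stem>_summary.json` holding
#' the per-region summary statistics.
#'
#' @param dists a list of `tacs_dist`.
#' @param stem path stem.
#' @return The stem, invisibly.
#' @export
write_distributions_csv <- function(dists, stem) {
  stopifnot(all(vapply(dists, inherits, TRUE, "tacs_dist")))
  long <- do.call(rbind, lapply(dists, function(d)
    data.frame(region = d$region, sample = d$samples)))
  utils::write.csv(long, paste0(stem, ".csv"), row.names = FALSE)
  summ <- lapply(dists, function(d)
    list(region = d$region, n = length(d$samples), mean = d$mean,
         squared_mean = d$squared_mean, skewness = d$skewness,
         kurtosis = d$kurtosis, n_modes = d$n_modes))
  jsonlite::write_json(summ, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Save / load a simulation result
#'
#' Plain-text archive: `<stem>_spikes.csv` (neuron, time_ms),
#' `<stem>_lfp.csv` (region x time), and `<stem>_meta.json` (dt, duration,
#' transient cut, seed).
#'
#' @param result a `tacs_sim`.
#' @param stem path stem.
#' @return `write_sim_result()`: the stem, invisibly. `read_sim_result()`:
#'   a `tacs_sim` (without the stimulus object).
#' @export
write_sim_result <- function(result, stem) {
  stopifnot(inherits(result, "tacs_sim"))
  utils::write.csv(result$spikes, paste0(stem, "_spikes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$lfp), paste0(stem, "_lfp.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(dt = result$dt, duration = result$duration,
                            transient_cut = result$transient_cut,
                            seed = result$seed,
                            n_regions = result$n_regions,
                            n_per_region = result$n_per_region),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_sim_result
#' @export
read_sim_result <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  lfp <- as.matrix(utils::read.csv(paste0(stem, "_lfp.csv")))
  dimnames(lfp) <- NULL
  structure(list(spikes = utils::read.csv(paste0(stem, "_spikes.csv")),
                 lfp = lfp, dt = meta$dt, duration = meta$duration,
                 transient_cut = meta$transient_cut, seed = meta$seed,
                 stim = NULL, n_regions = meta$n_regions,
                 n_per_region = meta$n_per_region),
            class = "tacs_sim")
}

#' Write / read a network model as JSON
#'
#' Doubles are written with 17 significant digits, so the reloaded model is
#' bit-identical to the original (same simulations for the same seed).
#'
#' @param model a `tacs_network`.
#' @param path output file.
#' @return `write_network_json()`: the path, invisibly.
#'   `read_network_json()`: a `tacs_network`.
#' @export
write_network_json <- function(model, path) {
  jsonlite::write_json(network_to_list(model), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  network_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
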