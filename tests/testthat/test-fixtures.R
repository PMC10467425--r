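test_that("flat sheet has identical unit normals", {
  m <- make_gyrified_mesh(n_gyri = 0, fold_depth = 0, sheet_size = 20,
                          resolution = 8, seed = 1)
  expect_true(all(abs(sqrt(rowSums(m$normals^2)) - 1) < 1e-9))
  ref <- m$normals[1, ]
  expect_true(all(abs(sweep(m$normals, 2, ref)) < 1e-9))
  expect_equal(ref, c(0, 0, -1))  # toward the white-matter side
})

test_that("mesh generation is deterministic and validates arguments", {
  a <- make_gyrified_mesh(3, 2, 30, 16, 3, seed = 7)
  b <- make_gyrified_mesh(3, 2, 30, 16, 3, seed = 7)
  expect_identical(a, b)
  expect_error(make_gyrified_mesh(3, 2, -1, 16), "positive")
  expect_error(make_gyrified_mesh(3, 2, 30, 2), "resolution")
  expect_error(make_gyrified_mesh(-1, 2, 30, 16), "n_gyri")
})

test_that("triangle normals agree with the analytic surface normal", {
  n_gyri <- 2; depth <- 2.5; size <- 40
  mean_angle <- function(res) {
    m <- make_gyrified_mesh(n_gyri, depth, size, resolution = res, seed = 1,
                            jitter = 0)
    # analytic normal of z = depth * sin(2 pi n x / L), oriented toward -z
    hp <- depth * 2 * pi * n_gyri / size *
      cos(2 * pi * n_gyri * m$centroids[, 1] / size)
    ana <- cbind(hp, 0, -1) / sqrt(1 + hp^2)
    mean(acos(pmin(1, rowSums(m$normals * ana))) * 180 / pi)
  }
  expect_lt(mean_angle(64), 1)
  expect_lt(mean_angle(128), mean_angle(64))  # first-order convergence

  m <- make_gyrified_mesh(n_gyri, depth, size, resolution = 64, seed = 1,
                          jitter = 0)
  # consistent orientation: adjacent triangles never flip sign
  expect_gt(min(rowSums(m$normals[seq(1, nrow(m$normals) - 1), , drop = FALSE] *
                          m$normals[seq(2, nrow(m$normals)), , drop = FALSE])), 0)
})

test_that("steep folds make in-plane projections bimodal with opposite-sign modes", {
  size <- 40; n_gyri <- 4
  depth <- 1.5 * size / (2 * pi * n_gyri)  # max slope 1.5 > tan(45 deg)
  m <- make_gyrified_mesh(n_gyri, depth, size, resolution = 64, seed = 1)
  f <- make_uniform_field(m, c(1, 0, 0), 0.2)
  comp <- project_normal(f, m)
  expect_gte(count_modes(comp), 2L)
  # the two dominant density peaks sit on opposite sides of zero, at the
  # same locations as for the analytic normal of the generating sinusoid
  top2 <- function(x) {
    d <- density(x)
    pk <- which(diff(sign(diff(d$y))) == -2) + 1
    sort(d$x[pk[order(d$y[pk], decreasing = TRUE)][1:2]])
  }
  got <- top2(comp)
  expect_lt(got[1], 0); expect_gt(got[2], 0)
  hp <- depth * 2 * pi * n_gyri / size *
    cos(2 * pi * n_gyri * m$centroids[, 1] / size)
  ana <- top2(0.2 * hp / sqrt(1 + hp^2))
  expect_equal(got, ana, tolerance = 0.05)
})

test_that("deeper folding shrinks |mean| and widens the projection spread", {
  size <- 40; n_gyri <- 4
  stats_at <- function(depth) {
    m <- make_gyrified_mesh(n_gyri, depth, size, resolution = 48, seed = 1)
    comp <- project_normal(make_uniform_field(m, c(1, 0, -1), 0.2), m)
    c(abs(mean(comp)), sd(comp))
  }
  ladder <- vapply(c(0.5, 1.5, 3, 5), stats_at, c(0, 0))
  expect_true(all(diff(ladder[1, ]) < 0))
  expect_true(all(diff(ladder[2, ]) > 0))
})

test_that("connectome invariants hold across random seeds", {
  for (seed in 1:10) {
    cn <- make_connectome(8, density = 0.6, weight_scale = 5, seed = seed)
    expect_identical(cn$weights, t(cn$weights))
    expect_identical(cn$lengths, t(cn$lengths))
    expect_true(all(diag(cn$weights) == 0) && all(diag(cn$lengths) == 0))
    expect_true(all(cn$weights >= 0))
    nz <- cn$lengths[cn$lengths > 0]
    expect_true(all(nz >= 15 & nz <= 180))
  }
  expect_identical(make_connectome(6, seed = 3), make_connectome(6, seed = 3))
})

test_that("full-density connectome has n(n-1)/2 connections", {
  cn <- make_connectome(22, density = 1, seed = 1)
  expect_equal(sum(cn$weights[upper.tri(cn$weights)] > 0), 231)
})

test_that("log2 linearizes the heavy-tailed node strengths", {
  cn <- make_connectome(40, density = 1, weight_scale = 10, seed = 2)
  strength <- rowSums(cn$weights)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew(strength), abs(skew(log2(strength))))
})

test_that("connectome rejects out-of-range tract lengths", {
  expect_error(make_connectome(5, length_range = c(10, 100)), "15")
  expect_error(make_connectome(5, length_range = c(20, 200)), "180")
  expect_error(make_connectome(1), "n_regions")
})

test_that("theoretical distributions match their declared shapes", {
  g <- make_theoretical_distribution("gaussian", 0, 1e5, seed = 1)
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(length(g)))

  bs <- make_theoretical_distribution("bimodal_symmetric", 0, 1e5, seed = 2)
  ds <- as_dist(bs)
  expect_equal(ds$n_modes, 2L)
  expect_lt(abs(ds$skewness), 0.1)

  ba <- make_theoretical_distribution("bimodal_asymmetric", 0, 1e5, seed = 3)
  da <- as_dist(ba)
  expect_equal(da$n_modes, 2L)
  expect_gt(abs(da$skewness), 0.2)
  # asymmetric mixture keeps the target mean
  expect_lt(abs(mean(ba)), 4 * sd(ba) / sqrt(length(ba)))

  shifted <- make_theoretical_distribution("gaussian", 0.05, 1e5, seed = 4)
  expect_lt(abs(mean(shifted) - 0.05), 4 * sd(shifted) / sqrt(length(shifted)))

  expect_error(make_theoretical_distribution("uniform"), "arg")
  expect_identical(make_theoretical_distribution("gaussian", 0, 100, seed = 5),
                   make_theoretical_distribution("gaussian", 0, 100, seed = 5))
})

test_that("target FC is a valid PLV matrix that decays with fiber length", {
  cn <- make_connectome(10, density = 1, seed = 1)
  fc <- make_target_fc(cn, decay_length = 60, noise_sd = 0, seed = 1)
  expect_identical(fc$plv, t(fc$plv))
  expect_true(all(diag(fc$plv) == 1))
  expect_true(all(fc$plv >= 0 & fc$plv <= 1))
  # equal lengths give equal PLV when noiseless
  L <- cn$lengths; ut <- which(upper.tri(L), arr.ind = TRUE)
  i <- ut[1, ]
  cn2 <- cn; cn2$lengths[3, 4] <- cn2$lengths[4, 3] <- L[i[1], i[2]]
  fc2 <- make_target_fc(cn2, decay_length = 60, noise_sd = 0, seed = 1)
  expect_equal(fc2$plv[3, 4], fc2$plv[i[1], i[2]])
  # slower decay raises mean off-diagonal PLV
  fc_fast <- make_target_fc(cn, decay_length = 20, noise_sd = 0, seed = 1)
  expect_gt(mean(fc$plv[upper.tri(fc$plv)]), mean(fc_fast$plv[upper.tri(fc_fast$plv)]))
})

test_that("synthetic cohort exposes the gyrification ladder", {
  cohort <- make_synthetic_cohort(n_subjects = 3, n_regions = 2,
                                  resolution = 16, seed = 1)
  expect_length(cohort, 3)
  for (s in cohort) {
    expect_s3_class(s$model, "tacs_network")
    expect_length(s$dists, 2)
  }
  # deeper-folded subjects have wider normal-component distributions
  spreads <- vapply(cohort, function(s) sd(s$dists[[1]]$samples), 1.0)
  expect_true(all(diff(spreads) > 0))
})

test_that("mesh and connectome round-trip through their text formats", {
  m <- make_gyrified_mesh(3, 2, 30, 12, 3, seed = 1)
  path <- tempfile(fileext = ".off")
  write_mesh_off(m, path)
  m2 <- read_mesh_off(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-7)
  expect_identical(m2$triangles, m$triangles)
  expect_identical(m2$region, m$region)
  expect_equal(m2$normals, m$normals, tolerance = 1e-7)

  cn <- make_connectome(6, density = 0.7, seed = 2)
  stem <- tempfile()
  write_connectome_csv(cn, stem)
  cn2 <- read_connectome_csv(stem)
  expect_equal(cn2$weights, cn$weights, tolerance = 1e-12)
  expect_equal(cn2$lengths, cn$lengths, tolerance = 1e-12)
})
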