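test_that("default design has 60 systematic + 20 random unique compositions", {
  d <- design_compositions(sim_config())
  expect_equal(nrow(d), 80)
  expect_equal(sum(d$tag == "systematic"), 60)
  expect_equal(sum(d$tag == "random"), 20)
  sys <- d[d$tag == "systematic", ]
  expect_equal(sum(sys$mixture_order <= 2), 30)   # edge cycle incl. vertices
  expect_equal(sum(sys$mixture_order == 3), 30)   # median interior points
  expect_true(all(abs(rowSums(d[, 1:3]) - 1) < 1e-12))
  # brute-force uniqueness scan over all pairs
  Y <- as.matrix(d[, 1:3])
  mind <- min(as.matrix(dist(Y))[upper.tri(diag(nrow(Y)))])
  expect_gt(mind, 1e-9)
})

test_that("small designs place each vertex once; centroid collisions error", {
  d <- design_compositions(clean_config(n_edge_points = 3, n_random = 0))
  expect_equal(nrow(d), 3 * 3 + 3 * 3)
  expect_equal(sum(d$mixture_order == 1), 3)      # each vertex exactly once
  expect_true(all(abs(rowSums(d[, 1:3]) - 1) < 1e-12))
  # when 3 divides n+1 the three medians all hit the centroid at t = 2/3
  expect_error(design_compositions(clean_config(n_edge_points = 2,
                                                n_random = 0)),
               "duplicate")
})

test_that("median points exclude the centroid and edge collisions", {
  d <- design_compositions(sim_config())
  sys3 <- d[d$tag == "systematic" & d$mixture_order == 3, 1:3]
  cent_dist <- apply(as.matrix(sys3), 1,
                     function(y) max(abs(y - 1 / 3)))
  expect_gt(min(cent_dist), 1e-6)
})

test_that("linear mixing: 50/50 binary equals the average of the pures", {
  g <- tiny_grid()
  comps <- data.frame(caffeine = c(1, 0, 0.5), quinic_acid = c(0, 1, 0.5),
                      nicotinic_acid = c(0, 0, 0))
  ds <- simulate_dataset(compositions = comps,
                         config = clean_config(replicates = 1), grid = g)
  A <- ds$absorbance
  expect_equal(A[3, ], (A[1, ] + A[2, ]) / 2, tolerance = 1e-12)
  # pure composition reproduces the library spectrum exactly
  S <- library_spectra(default_component_library(), g)
  expect_equal(A[1, ], unname(S["caffeine", ]), tolerance = 1e-12)
})

test_that("zero-nuisance simulation is exactly linear in the composition", {
  g <- tiny_grid()
  y1 <- c(0.7, 0.2, 0.1); y2 <- c(0.1, 0.3, 0.6); al <- 0.35
  comps <- rbind(y1, y2, al * y1 + (1 - al) * y2)
  comps <- data.frame(caffeine = comps[, 1], quinic_acid = comps[, 2],
                      nicotinic_acid = comps[, 3])
  ds <- simulate_dataset(compositions = comps,
                         config = clean_config(replicates = 1), grid = g)
  A <- ds$absorbance
  expect_equal(A[3, ], al * A[1, ] + (1 - al) * A[2, ], tolerance = 1e-9)
})

test_that("default simulation yields 480 records on the 540-point grid", {
  ds <- simulate_dataset()
  expect_equal(dim(ds$absorbance), c(480, 540))
  expect_equal(length(unique(ds$meta$sample_id)), 80)
  expect_true(all(table(ds$meta$sample_id) == 6))
})

test_that("same seed gives a bit-identical dataset, different seed does not", {
  cfg <- sim_config(seed = 5)
  d1 <- simulate_dataset(config = cfg, grid = tiny_grid())
  d2 <- simulate_dataset(config = cfg, grid = tiny_grid())
  expect_identical(d1$absorbance, d2$absorbance)
  d3 <- simulate_dataset(config = sim_config(seed = 6), grid = tiny_grid())
  expect_false(identical(d1$absorbance, d3$absorbance))
})

test_that("replicate mean converges to the noiseless spectrum", {
  g <- tiny_grid()
  comps <- data.frame(caffeine = 0.4, quinic_acid = 0.35,
                      nicotinic_acid = 0.25)
  noiseless <- simulate_dataset(compositions = comps,
                                config = clean_config(replicates = 1),
                                grid = g)$absorbance[1, ]
  noisy <- simulate_dataset(compositions = comps,
                            config = clean_config(replicates = 1000,
                                                  noise_sd = 0.05),
                            grid = g)
  mean_spec <- colMeans(noisy$absorbance)
  tol <- 3 * 0.05 / sqrt(1000)
  expect_gte(mean(abs(mean_spec - noiseless) <= tol), 0.99)
})

test_that("thickness jitter and baseline draws are recorded per replicate", {
  cfg <- clean_config(replicates = 4, baseline_xi_range = c(0.1, 0.4),
                      thickness_jitter = 0.05)
  comps <- data.frame(caffeine = 1, quinic_acid = 0, nicotinic_acid = 0)
  ds <- simulate_dataset(compositions = comps, config = cfg,
                         grid = tiny_grid())
  xi <- attr(ds, "xi_true")
  expect_length(xi, 4)
  expect_true(all(xi >= 0.1 & xi <= 0.4))
  expect_length(unique(attr(ds, "thickness")), 4)
})

test_that("negative chemical amplitudes are clipped with a warning", {
  lib <- component_library(
    peaks = list(caffeine = rbind(c(1.0, 0.05, 0.5)),
                 quinic_acid = rbind(c(1.5, 0.05, 0.5)),
                 nicotinic_acid = rbind(c(2.0, 0.05, 0.5))),
    slope = c(caffeine = -0.5, quinic_acid = 0, nicotinic_acid = 0))
  comps <- data.frame(caffeine = 1, quinic_acid = 0, nicotinic_acid = 0)
  expect_warning(
    simulate_dataset(lib, comps, clean_config(replicates = 1), tiny_grid()),
    "clipped")
})

test_that("component libraries must be mutually distinguishable", {
  pk <- rbind(c(1.0, 0.05, 0.5))
  expect_error(component_library(peaks = list(caffeine = pk, quinic_acid = pk,
                                              nicotinic_acid = pk)),
               "distinguishable")
})
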