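test_that("Qext matches the independent Bessel-function oracle", {
  ms <- c(1.33, 1.5, 1.54, 2.0)
  xs <- c(0.1, 0.5, 1, 2, 5, 10, 15, 20)
  pairs <- expand.grid(m = ms, x = xs)[seq_len(20), ]
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$m[i]; x <- pairs$x[i]
    got <- thzchem:::mie_qext_one(complex(real = m), x)
    want <- qext_bessel_oracle(m, x)
    expect_equal(got, want, tolerance = 1e-8,
                 label = sprintf("Qext(m=%g, x=%g)", m, x))
  }
})

test_that("Qext vanishes for a vanishing scatterer", {
  q <- mie_extinction_efficiency(mie_params(radius_um = 0.01), 0.3)
  expect_lt(q, 1e-6)
})

test_that("Qext approaches the extinction-paradox limit of 2 at large x", {
  got <- thzchem:::mie_qext_one(1.5 + 0i, 50)
  expect_equal(got, qext_bessel_oracle(1.5, 50), tolerance = 1e-6)
  expect_lt(abs(got - 2) / 2, 0.15)
})

test_that("Mie parameter and frequency validation", {
  expect_error(mie_params(radius_um = 0), "radius")
  expect_error(mie_extinction_efficiency(mie_params(), c(1, -0.2)),
               "positive")
})

test_that("valid mask keeps exactly the points above the low cut", {
  g <- thz_grid()
  m0 <- valid_frequency_mask(g, water_lines = numeric(0))
  expect_equal(sum(m0$mask), 490)
  expect_true(all(g$frequencies[m0$mask] > 0.55))

  m1 <- valid_frequency_mask(g, water_lines = 1.0, halfwidth = 0.025)
  excluded <- g$frequencies[!m1$mask & g$frequencies > 0.55]
  expect_equal(excluded, seq(0.975, 1.025, by = 0.005), tolerance = 1e-9)

  m2 <- valid_frequency_mask(g, water_lines = 1.0, halfwidth = 0)
  expect_equal(sum(!m2$mask & g$frequencies > 0.55), 1)

  expect_error(valid_frequency_mask(g, water_lines = numeric(0),
                                    low_cut = c(0.3, 3.5)),
               "empty")
})

test_that("baseline coefficient: proportional, trough, and clipped cases", {
  g <- thz_grid()
  q <- mie_extinction_efficiency(mie_params(), g)
  mask <- valid_frequency_mask(g, water_lines = numeric(0))
  expect_equal(fit_baseline_coefficient(3 * q, q, mask), 3, tolerance = 1e-12)

  # peaks riding above the baseline except one trough at 0.7 * Qext
  a <- q + 0.5 * exp(-(g$frequencies - 2)^2 / 0.02)
  trough <- which(mask$mask)[100]
  a[trough] <- 0.7 * q[trough]
  xi <- fit_baseline_coefficient(a, q, mask)
  expect_equal(xi, 0.7, tolerance = 1e-12)
  # dense 1-D grid search oracle over xi confirms the penalty optimum
  M <- 1e6 * max(a) / min(q[mask$mask])
  obj <- function(z) {
    r <- a[mask$mask] - z * q[mask$mask]
    sum(r) + M * sum(pmax(0, -r))
  }
  grid_xi <- seq(0, 1.5, length.out = 4001)
  expect_equal(xi, grid_xi[which.min(sapply(grid_xi, obj))],
               tolerance = 1e-3)

  a2 <- q; a2[trough] <- -0.1
  expect_warning(xi2 <- fit_baseline_coefficient(a2, q, mask), "clipped")
  expect_equal(xi2, 0)
})

test_that("penalty and closed-form coefficients agree on random spectra", {
  g <- thz_grid()
  q <- mie_extinction_efficiency(mie_params(), g)
  mask <- valid_frequency_mask(g)
  set.seed(42)
  for (i in 1:100) {
    a <- 0.5 * runif(1) * q + abs(rnorm(540, sd = 0.2)) + 0.01
    xi_p <- fit_baseline_coefficient(a, q, mask, method = "penalty")
    xi_c <- fit_baseline_coefficient(a, q, mask, method = "closed_form")
    expect_lt(abs(xi_p - xi_c), 1e-6)
  }
})

test_that("baseline fit is scale-equivariant and mask-monotone", {
  g <- thz_grid()
  q <- mie_extinction_efficiency(mie_params(), g)
  mask_small <- valid_frequency_mask(g, water_lines = thz_water_lines())
  mask_big <- valid_frequency_mask(g, water_lines = numeric(0))
  set.seed(9)
  for (i in 1:20) {
    a <- 0.3 * q + abs(rnorm(540, sd = 0.1)) + 0.05
    xi <- fit_baseline_coefficient(a, q, mask_big)
    expect_equal(fit_baseline_coefficient(2.5 * a, q, mask_big), 2.5 * xi,
                 tolerance = 1e-10)
    # shrinking the valid set can only raise (or preserve) the minimum ratio
    expect_gte(fit_baseline_coefficient(a, q, mask_small), xi - 1e-12)
  }
})

test_that("multifactor removal zeroes pure-baseline spectra; single factor leaves residues", {
  g <- thz_grid()
  q <- mie_extinction_efficiency(mie_params(), g)
  mask <- valid_frequency_mask(g)
  cs <- c(0.2, 0.5, 1.1)
  meta <- data.frame(sample_id = c("a", "b", "c"), replicate = 1L,
                     caffeine = 1, quinic_acid = 0, nicotinic_acid = 0)
  ds <- thz_dataset(g, outer(cs, q), meta)
  multi <- remove_baseline(ds, mask = mask, mode = "multifactor")
  expect_lt(max(abs(multi$train$absorbance)), 1e-10)
  single <- remove_baseline(ds, mask = mask, mode = "single_factor")
  expect_equal(single$xi_train, rep(min(cs), 3))
  expect_equal(single$train$absorbance, outer(cs - min(cs), q),
               tolerance = 1e-10)
})

test_that("injected baseline coefficients are recovered exactly without noise", {
  cfg <- clean_config(n_edge_points = 4, n_random = 5, replicates = 2,
                      baseline_xi_range = c(0.05, 0.4))
  ds <- simulate_dataset(compositions = design_compositions(cfg),
                         config = cfg)
  mask <- valid_frequency_mask(ds$grid)
  bl <- remove_baseline(ds, mask = mask, mode = "multifactor")
  expect_lt(max(abs(bl$xi_train - attr(ds, "xi_true"))), 1e-6)
  # feasibility: corrected absorbance never dips below zero on the valid set
  expect_gte(min(bl$train$absorbance[, mask$mask]), -1e-9)
})

test_that("multifactor_concat returns one xi per record in record order", {
  cfg <- clean_config(n_edge_points = 3, n_random = 2, replicates = 3,
                      baseline_xi_range = c(0.1, 0.2))
  ds <- simulate_dataset(compositions = design_compositions(cfg),
                         config = cfg)
  bl <- remove_baseline(ds, mask = valid_frequency_mask(ds$grid),
                        mode = "multifactor_concat")
  expect_length(bl$xi_train, nrow(ds$absorbance))
  expect_equal(bl$xi_train, attr(ds, "xi_true"), tolerance = 1e-6)
})

test_that("apply-set grid mismatch is rejected", {
  cfg <- clean_config(n_edge_points = 3, n_random = 0, replicates = 1)
  comps <- design_compositions(cfg)
  ds1 <- simulate_dataset(compositions = comps, config = cfg)
  ds2 <- simulate_dataset(compositions = comps, config = cfg,
                          grid = tiny_grid())
  expect_error(remove_baseline(ds1, ds2,
                               mask = valid_frequency_mask(ds1$grid),
                               mode = "multifactor"),
               "grid")
})
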