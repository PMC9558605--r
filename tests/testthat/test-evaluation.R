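small_dataset <- function(noise = 0, seed = 7, ...) {
  cfg <- clean_config(n_edge_points = 4, n_random = 6, replicates = 2,
                      noise_sd = noise, seed = seed, ...)
  simulate_dataset(compositions = design_compositions(cfg), config = cfg,
                   grid = tiny_grid())
}

test_that("fold assignment pins unitary/binary samples and balances ternary ones", {
  ds <- simulate_dataset()            # full 80-sample design
  folds <- assign_folds(ds, k = 5, seed = 3)
  fold_of <- folds$fold[match(ds$meta$sample_id, folds$sample_id)]
  # each test fold holds 60 spectra; every training set holds 420
  for (j in 1:5) {
    expect_equal(sum(fold_of == j, na.rm = TRUE), 60)
    expect_equal(sum(is.na(fold_of) | fold_of != j), 420)
  }
  # all order <= 2 spectra are always-train
  expect_equal(sum(is.na(fold_of)), 180)
  expect_true(all(ds$meta$mixture_order[is.na(fold_of)] <= 2))
  # replicates never straddle folds
  per_sample <- tapply(fold_of, ds$meta$sample_id,
                       function(v) length(unique(v)))
  expect_true(all(per_sample == 1))
  # test folds partition the ternary spectra exactly
  tern <- which(ds$meta$mixture_order == 3)
  expect_setequal(tern, which(!is.na(fold_of)))
})

test_that("degenerate k gives leave-one-sample-out and seeds reshuffle only", {
  ds <- small_dataset()
  n_tern <- length(unique(ds$meta$sample_id[ds$meta$mixture_order == 3]))
  loso <- assign_folds(ds, k = n_tern, seed = 1)
  fold_of <- loso$fold[match(ds$meta$sample_id, loso$sample_id)]
  expect_true(all(table(fold_of) == 2))   # replicate count per test fold
  f1 <- assign_folds(ds, k = 3, seed = 1)
  f2 <- assign_folds(ds, k = 3, seed = 2)
  expect_false(identical(f1$fold, f2$fold))
  expect_equal(sort(table(f1$fold)), sort(table(f2$fold)))
  expect_error(assign_folds(ds, k = 1), "k must be")
})

test_that("rmse pools records and analytes", {
  expect_equal(rmse(diag(3), diag(3)), 0)
  expect_equal(rmse(matrix(c(0.5, 0.3, 0.2), 1), matrix(c(0.4, 0.4, 0.2), 1)),
               sqrt((0.01 + 0.01 + 0) / 3))
  expect_equal(rmse(matrix(0.3, 4, 3), matrix(0.3 - 0.07, 4, 3)), 0.07)
  expect_error(rmse(matrix(0, 0, 3), matrix(0, 0, 3)), "empty")
})

test_that("noiseless linear data is solved by the plsr reference pipeline", {
  ds <- small_dataset()
  folds <- assign_folds(ds, k = 5, seed = 2)
  r <- run_pipeline(pipeline_spec(model = model_spec("plsr", ncomp = 3)),
                    ds, folds)
  expect_lt(r$rmsep, 1e-3)
  expect_lt(r$rmsec, 1e-3)
})

test_that("explicit bypass stages equal the implicit raw-feature path", {
  ds <- small_dataset(noise = 0.01)
  folds <- assign_folds(ds, k = 3, seed = 2)
  r1 <- run_pipeline(pipeline_spec(model = model_spec("plsr", ncomp = 3)),
                     ds, folds)
  r2 <- run_pipeline(pipeline_spec(normalizer = "none", baseline = "none",
                                   reducer = reducer_spec("none"),
                                   model = model_spec("plsr", ncomp = 3)),
                     ds, folds)
  expect_equal(r1$rmsep, r2$rmsep, tolerance = 1e-12)
  expect_equal(r1$per_fold, r2$per_fold, tolerance = 1e-12)
})

test_that("pooled RMSE identity holds across folds", {
  ds <- small_dataset(noise = 0.02)
  folds <- assign_folds(ds, k = 3, seed = 5)
  r <- run_pipeline(pipeline_spec(model = model_spec("plsr", ncomp = 3)),
                    ds, folds)
  lhs <- r$rmsep^2 * sum(r$per_fold$n_test)
  rhs <- sum(r$per_fold$rmsep^2 * r$per_fold$n_test)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("pipeline evaluation is reproducible end to end", {
  ds <- small_dataset(noise = 0.01)
  folds <- assign_folds(ds, k = 3, seed = 9)
  spec <- pipeline_spec(normalizer = "zscore",
                        reducer = reducer_spec("pca", n_components = 5),
                        model = model_preset("mlp-table2", seed = 4),
                        seed = 4)
  r1 <- run_pipeline(spec, ds, folds)
  r2 <- run_pipeline(spec, ds, folds)
  expect_equal(r1$rmsep, r2$rmsep, tolerance = 1e-12)
  expect_equal(r1$rmsec, r2$rmsec, tolerance = 1e-12)
})

test_that("pooled RMSEP is nondecreasing in the noise level", {
  folds <- NULL
  rmseps <- sapply(c(0, 0.02, 0.1), function(noise) {
    vals <- sapply(1:3, function(s) {
      ds <- small_dataset(noise = noise, seed = s)
      if (is.null(folds)) folds <<- assign_folds(ds, k = 3, seed = 1)
      run_pipeline(pipeline_spec(model = model_spec("plsr", ncomp = 3)),
                   ds, folds)$rmsep
    })
    mean(vals)
  })
  expect_true(all(diff(rmseps) > 0))
})

test_that("grid search ranks deterministically and records failures", {
  ds <- small_dataset(noise = 0.01)
  folds <- assign_folds(ds, k = 3, seed = 2)
  specs <- list(
    pipeline_spec(model = model_spec("plsr", ncomp = 3)),
    pipeline_spec(normalizer = "zscore", model = model_spec("plsr", ncomp = 3)),
    pipeline_spec(normalizer = "minmax", model = model_spec("plsr", ncomp = 3)),
    pipeline_spec(reducer = reducer_spec("pca", n_components = 4),
                  model = model_spec("plsr", ncomp = 3)))
  g1 <- grid_search(specs, ds, folds)
  expect_length(g1$results, 4)
  expect_equal(g1$table$rmsep, sort(g1$table$rmsep))
  g2 <- grid_search(rev(specs), ds, folds)
  expect_equal(g1$table, g2$table)
  single <- grid_search(specs[1], ds, folds)
  expect_equal(single$table$rmsep,
               run_pipeline(specs[[1]], ds, folds)$rmsep)
  # an unrunnable spec is recorded, not fatal
  bad <- pipeline_spec(reducer = reducer_spec("pca", n_components = 4000),
                       model = model_spec("plsr", ncomp = 3))
  g3 <- grid_search(list(specs[[1]], bad), ds, folds)
  expect_length(g3$results, 1)
  expect_length(g3$failures, 1)
})

test_that("preprocessing effect reports matched-pair deltas only", {
  ds <- small_dataset(noise = 0.02)
  folds <- assign_folds(ds, k = 3, seed = 2)
  mk <- function(...) pipeline_spec(..., model = model_spec("plsr", ncomp = 3))
  res <- grid_search(list(mk(), mk(normalizer = "zscore"),
                          mk(normalizer = "minmax"),
                          mk(reducer = reducer_spec("pca", n_components = 4))),
                     ds, folds)$results
  rep_ <- preprocessing_effect(res)
  by_rmsep <- sapply(res, function(r) r$rmsep)
  labels <- sapply(res, function(r) r$spec$label)
  base <- by_rmsep[labels == "none/none/none/plsr"]
  z <- by_rmsep[labels == "none/zscore/none/plsr"]
  row <- rep_[rep_$technique == "zscore" & rep_$family == "plsr", ]
  expect_equal(row$mean_delta, z - base, tolerance = 1e-12)
  expect_equal(row$n_pairs, 1)
  # a technique with no matching bypass shows zero pairs and NA delta
  only <- preprocessing_effect(res[2])
  r2 <- only[only$technique == "zscore", ]
  expect_equal(r2$n_pairs, 0)
  expect_true(is.na(r2$mean_delta))
})

test_that("effect deltas vanish for a dataset already scaled to the unit interval", {
  ds <- small_dataset(noise = 0.01)
  # rescale every feature into [0, 1] and pin the extrema onto the two
  # replicates of one always-train (unitary) sample, so the training block
  # of every fold attains 0 and 1 per feature and minmax is the identity
  A <- ds$absorbance
  A <- sweep(A, 2, apply(A, 2, min))
  A <- sweep(A, 2, pmax(apply(A, 2, max), 1e-12), "/")
  pin <- which(ds$meta$mixture_order == 1)[1:2]
  A[pin[1], ] <- 0; A[pin[2], ] <- 1
  ds2 <- thz_dataset(ds$grid, A, ds$meta[, c("sample_id", "replicate",
                                             "caffeine", "quinic_acid",
                                             "nicotinic_acid", "tag")])
  folds <- assign_folds(ds2, k = 3, seed = 2)
  mk <- function(...) pipeline_spec(..., model = model_spec("plsr", ncomp = 3))
  res <- grid_search(list(mk(), mk(normalizer = "minmax")), ds2, folds)$results
  rep_ <- preprocessing_effect(res)
  row <- rep_[rep_$technique == "minmax" & rep_$family == "plsr", ]
  expect_lt(abs(row$mean_delta), 1e-6)
})

test_that("linearity table has one row per seed with paired deltas", {
  ds <- small_dataset(noise = 0.02)
  folds <- assign_folds(ds, k = 3, seed = 2)
  tab <- linearity_comparison(ds, folds, seeds = c(3, 4))
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("seed", "rmsep_tanh", "rmsep_identity", "delta",
                      "pct_diff"))
  expect_equal(tab$delta, tab$rmsep_tanh - tab$rmsep_identity)
})
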