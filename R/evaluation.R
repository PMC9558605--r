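#' Grouped fold assignment with boundary samples pinned to training
#'
#' Ternary samples (mixture order 3) are shuffled by `seed` and dealt
#' round-robin into `k` folds; unitary and binary samples (order <= 2) are
#' marked ALWAYS_TRAIN, so they sit in every training set and provide the
#' composition extrema between which ternary mixtures are interpolated.
#' All replicates of a sample share its assignment -- splitting replicates
#' across folds would leak near-duplicate spectra into the test sets.
#'
#' @param dataset A `thz_dataset`.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return Object of class `thz_folds`: data frame `sample_id`, `fold`
#'   (integer, `NA` = always train), with attribute `k`.
#' @export
assign_folds <- function(dataset, k = 5, seed = 1) {
  stopifnot(inherits(dataset, "thz_dataset"))
  m <- dataset$meta
  samp <- unique(m[, c("sample_id", "mixture_order")])
  ternary <- samp$sample_id[samp$mixture_order == 3]
  if (k < 2 || k > length(ternary))
    stop("k must be in [2, number of ternary samples]")
  shuffled <- local_seed(seed, sample(ternary))
  fold <- rep(seq_len(k), length.out = length(shuffled))
  out <- data.frame(sample_id = samp$sample_id,
                    fold = NA_integer_)
  out$fold[match(shuffled, out$sample_id)] <- fold
  structure(out, k = as.integer(k), class = c("thz_folds", "data.frame"))
}

#' Pooled root-mean-square error
#'
#' RMSE pooled over all records and all three analytes: the square root of
#' the mean squared residual across every entry of the matrices.
#'
#' @param predicted,actual Equal-shaped composition matrices.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, actual) {
  predicted <- as.matrix(predicted); actual <- as.matrix(actual)
  if (!all(dim(predicted) == dim(actual)))
    stop("predicted and actual must have equal shapes")
  if (length(predicted) == 0) stop("empty input")
  sqrt(mean((predicted - actual)^2))
}

#' Declare one pipeline combination
#'
#' One point of the combinatorial study: a baseline mode, a normalizer, a
#' reducer, and a model. Baseline removal (when enabled) runs first on the
#' raw spectra, then the normalizer, then the reducer, then the model; each
#' stage has an explicit bypass (`"none"`). Every stage is fitted on the
#' training block of each fold only.
#'
#' @param normalizer `"none"`, `"zscore"`, or `"minmax"`.
#' @param baseline `"none"`, `"single_factor"`, `"multifactor"`, or
#'   `"multifactor_concat"`.
#' @param reducer A [reducer_spec()].
#' @param model A [model_spec()] or preset name.
#' @param mie [mie_params()] for the baseline stage.
#' @param mask Optional [valid_frequency_mask()]; built from the dataset
#'   grid with defaults when omitted.
#' @param seed Pipeline seed (propagated to stochastic stages).
#' @param label Optional display label; autogenerated otherwise.
#' @return Object of class `thz_pipeline_spec`.
#' @export
pipeline_spec <- function(normalizer = "none", baseline = "none",
                          reducer = reducer_spec("none"),
                          model = model_preset("plsr-table2"),
                          mie = mie_params(), mask = NULL, seed = 1L,
                          label = NULL) {
  normalizer <- match.arg(normalizer, c("none", "zscore", "minmax"))
  baseline <- match.arg(baseline, c("none", "single_factor", "multifactor",
                                    "multifactor_concat"))
  if (is.character(model)) model <- model_preset(model, seed = seed)
  stopifnot(inherits(reducer, "thz_reducer_spec"),
            inherits(model, "thz_model_spec"))
  if (reducer$concat_xi && baseline != "multifactor_concat")
    stop("concat_xi requires baseline mode multifactor_concat")
  if (baseline == "multifactor_concat" && !reducer$concat_xi)
    stop("baseline mode multifactor_concat requires a concat_xi reducer")
  if (reducer$method == "nmf" && normalizer != "minmax" &&
      baseline == "none")
    stop("nmf needs non-negative inputs: use the minmax normalizer or Mie baseline removal")
  if (is.null(label))
    label <- paste(baseline, normalizer, reducer$method, model$family,
                   sep = "/")
  structure(list(normalizer = normalizer, baseline = baseline,
                 reducer = reducer, model = model, mie = mie, mask = mask,
                 seed = as.integer(seed), label = label),
            class = "thz_pipeline_spec")
}

# fit all stages on a training block, apply to train + test; returns preds
run_fold <- function(spec, train, test, qext, mask) {
  Xtr <- train$absorbance; Xte <- test$absorbance
  xi_tr <- NULL; xi_te <- NULL
  if (spec$baseline != "none") {
    mode <- spec$baseline
    bl <- remove_baseline(train, test, params = spec$mie, mask = mask,
                          mode = mode, qext = qext)
    Xtr <- bl$train$absorbance; Xte <- bl$apply$absorbance
    if (mode == "multifactor_concat") {
      xi_tr <- bl$xi_train; xi_te <- bl$xi_apply
    }
  }
  norm <- fit_normalizer(Xtr, spec$normalizer)
  Xtr <- apply_normalizer(norm, Xtr); Xte <- apply_normalizer(norm, Xte)
  red <- fit_reducer(Xtr, spec$reducer)
  Ztr <- apply_reducer(red, Xtr, xi = xi_tr)
  Zte <- apply_reducer(red, Xte, xi = xi_te)
  mod <- train_model(spec$model, Ztr, composition_matrix(train))
  list(pred_train = predict(mod, Ztr), pred_test = predict(mod, Zte))
}

#' Evaluate one pipeline under the grouped cross-validation design
#'
#' For each fold, every stage is fitted on the training spectra only
#' (always-train samples plus the ternary samples outside the fold),
#' then applied to the training block (RMSEC) and the held-out fold
#' (RMSEP). The headline figures pool residuals: pooled RMSEP is the RMSE
#' over all test residuals across folds (each ternary spectrum is tested
#' exactly once), not the mean of fold RMSEPs; fold-level values and a
#' per-analyte breakdown are reported alongside.
#'
#' @param spec A [pipeline_spec()].
#' @param dataset A `thz_dataset`.
#' @param folds A [assign_folds()] result for `dataset`.
#' @return Object of class `thz_eval`: list with `spec`, `per_fold` data
#'   frame (`fold`, `n_train`, `n_test`, `rmsec`, `rmsep`), `rmsec`,
#'   `rmsep` (pooled), `rmsep_analyte`, `rmsec_analyte`, `provenance`.
#' @export
run_pipeline <- function(spec, dataset, folds) {
  stopifnot(inherits(spec, "thz_pipeline_spec"),
            inherits(dataset, "thz_dataset"), inherits(folds, "thz_folds"))
  k <- attr(folds, "k")
  fold_of <- folds$fold[match(dataset$meta$sample_id, folds$sample_id)]
  mask <- spec$mask
  if (is.null(mask) && spec$baseline != "none")
    mask <- valid_frequency_mask(dataset$grid)
  qext <- if (spec$baseline != "none")
    mie_extinction_efficiency(spec$mie, dataset$grid)
  per_fold <- vector("list", k)
  res_test <- list(); res_train <- list()
  for (j in seq_len(k)) {
    te_idx <- which(fold_of == j & !is.na(fold_of))
    tr_idx <- which(is.na(fold_of) | fold_of != j)
    train <- subset_records(dataset, tr_idx)
    test <- subset_records(dataset, te_idx)
    out <- tryCatch(
      run_fold(spec, train, test, qext, mask),
      error = function(e) stop(sprintf("fold %d failed in pipeline '%s': %s",
                                       j, spec$label, conditionMessage(e)),
                               call. = FALSE))
    Ytr <- composition_matrix(train); Yte <- composition_matrix(test)
    per_fold[[j]] <- data.frame(fold = j, n_train = nrow(Ytr),
                                n_test = nrow(Yte),
                                rmsec = rmse(out$pred_train, Ytr),
                                rmsep = rmse(out$pred_test, Yte))
    res_test[[j]] <- out$pred_test - Yte
    res_train[[j]] <- out$pred_train - Ytr
  }
  Rte <- do.call(rbind, res_test); Rtr <- do.call(rbind, res_train)
  structure(list(
    spec = spec,
    per_fold = do.call(rbind, per_fold),
    rmsec = sqrt(mean(Rtr^2)),
    rmsep = sqrt(mean(Rte^2)),
    rmsec_analyte = sqrt(colMeans(Rtr^2)),
    rmsep_analyte = stats::setNames(sqrt(colMeans(Rte^2)), analyte_names),
    provenance = list(label = spec$label, seed = spec$seed, k = k,
                      n_records = nrow(dataset$absorbance),
                      dataset_checksum = dataset_checksum(dataset))),
    class = "thz_eval")
}

#' @export
print.thz_eval <- function(x, ...) {
  cat(sprintf("<thz_eval> %s  RMSEC %.4g  RMSEP %.4g (pooled, %d folds)\n",
              x$spec$label, x$rmsec, x$rmsep, nrow(x$per_fold)))
  invisible(x)
}

dataset_checksum <- function(dataset) {
  v <- c(dataset$absorbance)
  sprintf("%.10e", sum(v * seq_along(v) %% 97) + sum(v))
}

#' Evaluate a grid of pipeline combinations
#'
#' Runs [run_pipeline()] for every spec; individual failures are recorded
#' and do not abort the run. Results are ranked by pooled RMSEP ascending,
#' ties broken by pooled RMSEC, then by label, so the ranking is invariant
#' to the enumeration order of the grid.
#'
#' @param specs List of [pipeline_spec()] objects.
#' @param dataset A `thz_dataset`.
#' @param folds A [assign_folds()] result.
#' @return List with `results` (ranked `thz_eval` objects), `table` (ranked
#'   summary data frame), and `failures` (named error messages).
#' @export
grid_search <- function(specs, dataset, folds) {
  stopifnot(length(specs) >= 1)
  evals <- list(); failures <- character()
  for (s in specs) {
    r <- tryCatch(run_pipeline(s, dataset, folds), error = function(e) e)
    if (inherits(r, "error")) failures[s$label] <- conditionMessage(r)
    else evals[[length(evals) + 1]] <- r
  }
  if (length(evals)) {
    tab <- data.frame(label = vapply(evals, function(r) r$spec$label, ""),
                      rmsec = vapply(evals, function(r) r$rmsec, 0),
                      rmsep = vapply(evals, function(r) r$rmsep, 0))
    ord <- order(tab$rmsep, tab$rmsec, tab$label)
    evals <- evals[ord]; tab <- tab[ord, ]; rownames(tab) <- NULL
  } else tab <- NULL
  list(results = evals, table = tab, failures = failures)
}

#' Mean change in RMSEP attributable to each preprocessing technique
#'
#' For every evaluated combination that uses a technique (a normalizer, the
#' Mie baseline removal, or a reducer method), finds the matched
#' combination identical except for that technique replaced by its bypass,
#' and averages the paired differences `RMSEP_with - RMSEP_without` per
#' (technique, model family). Negative values mean the technique improved
#' prediction. Only exact matched pairs enter; cells without pairs are
#' reported with `n_pairs = 0` and `NA` delta, never imputed.
#'
#' @param results List of `thz_eval` objects (e.g. `grid_search()$results`).
#' @return Data frame `technique`, `family`, `mean_delta`, `n_pairs`, of
#'   class `thz_effect_report`.
#' @export
preprocessing_effect <- function(results) {
  stopifnot(length(results) >= 1)
  info <- lapply(results, function(r) {
    s <- r$spec
    list(norm = s$normalizer, base = s$baseline,
         red = s$reducer$method,
         red_id = paste(s$reducer$method, s$reducer$n_components,
                        s$reducer$n_neighbors %||% "", sep = ":"),
         model_id = paste(s$model$family,
                          paste(names(s$model$params),
                                unlist(lapply(s$model$params, paste,
                                              collapse = "+")),
                                sep = "=", collapse = ";"),
                          s$model$seed, sep = "|"),
         family = s$model$family, seed = s$seed, rmsep = r$rmsep)
  })
  key <- function(x, norm, base, red_id)
    paste(norm, base, red_id, x$model_id, x$seed, sep = "||")
  all_keys <- vapply(info, function(x) key(x, x$norm, x$base, x$red_id), "")
  rows <- list()
  add <- function(technique, fam, deltas) {
    rows[[length(rows) + 1]] <<- data.frame(
      technique = technique, family = fam,
      mean_delta = if (length(deltas)) mean(deltas) else NA_real_,
      n_pairs = length(deltas))
  }
  fams <- unique(vapply(info, `[[`, "", "family"))
  norm_techs <- c(zscore = "zscore", minmax = "minmax")
  for (fam in fams) {
    idx <- which(vapply(info, `[[`, "", "family") == fam)
    # normalization techniques vs no-normalization bypass
    for (tech in names(norm_techs)) {
      deltas <- numeric()
      for (i in idx) {
        x <- info[[i]]
        if (x$norm != tech) next
        m <- which(all_keys == key(x, "none", x$base, x$red_id))
        if (length(m) == 1)
          deltas <- c(deltas, x$rmsep - info[[m]]$rmsep)
      }
      add(tech, fam, deltas)
    }
    # Mie baseline removal vs no-baseline bypass
    deltas <- numeric()
    for (i in idx) {
      x <- info[[i]]
      if (x$base == "none") next
      m <- which(all_keys == key(x, x$norm, "none", x$red_id))
      if (length(m) == 1)
        deltas <- c(deltas, x$rmsep - info[[m]]$rmsep)
    }
    add("mie", fam, deltas)
    # reducers vs no-reduction bypass
    reds <- setdiff(unique(vapply(info[idx], `[[`, "", "red")), "none")
    for (tech in reds) {
      deltas <- numeric()
      for (i in idx) {
        x <- info[[i]]
        if (x$red != tech) next
        m <- which(all_keys == key(x, x$norm, x$base, "none::"))
        if (length(m) == 1)
          deltas <- c(deltas, x$rmsep - info[[m]]$rmsep)
      }
      add(tech, fam, deltas)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("thz_effect_report", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear vs nonlinear calibration comparison
#'
#' Trains the tanh-activation and identity-activation MLP variants (no
#' normalization, no reduction) on identical folds for each seed and
#' reports the paired pooled RMSEPs. A consistently lower tanh RMSEP
#' indicates a nonlinear relationship between spectra and composition.
#'
#' @param dataset A `thz_dataset`.
#' @param folds A [assign_folds()] result.
#' @param seeds Integer vector of model seeds.
#' @return Data frame, one row per seed: `seed`, `rmsep_tanh`,
#'   `rmsep_identity`, `delta` (tanh - identity), `pct_diff` (relative to
#'   identity, percent).
#' @export
linearity_comparison <- function(dataset, folds, seeds = 1:5) {
  stopifnot(length(seeds) >= 1)
  rows <- lapply(seeds, function(s) {
    r_tanh <- run_pipeline(pipeline_spec(model = model_preset("mlp-tanh",
                                                              seed = s),
                                         seed = s),
                           dataset, folds)
    r_id <- run_pipeline(pipeline_spec(model = model_preset("mlp-linear",
                                                            seed = s),
                                       seed = s),
                         dataset, folds)
    data.frame(seed = s, rmsep_tanh = r_tanh$rmsep,
               rmsep_identity = r_id$rmsep,
               delta = r_tanh$rmsep - r_id$rmsep,
               pct_diff = 100 * (r_tanh$rmsep - r_id$rmsep) / r_id$rmsep)
  })
  do.call(rbind, rows)
}
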