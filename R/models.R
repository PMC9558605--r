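#' Declare a calibration model
#'
#' One uniform train/predict contract over five families. All three mass
#' ratios are predicted jointly where the family supports multi-output
#' regression (plsr, mlp, cnn); natively single-output families (svr,
#' gboost) train one regressor per analyte, recorded in the fitted model.
#'
#' Recognized hyperparameters by family:
#' * `plsr`: `ncomp` (>= 1), `prescale` (internal standardization of X).
#' * `svr`: `nu` in (0, 1], `cost`, `gamma` (`"auto"` = 1/n_features),
#'   `kernel`.
#' * `mlp`: `hidden` (neurons in the single hidden layer), `activation`
#'   (`"logistic"`, `"tanh"`, `"identity"`), `out_activation`
#'   (`"identity"` or `"tanh"`), `alpha` (L2 penalty), `maxit`.
#' * `cnn`: `filters`, `kernel`, `stride`, `epochs`, `lr`.
#' * `gboost`: `eta`, `max_depth`, `min_child_weight`, `gamma`,
#'   `subsample`, `colsample_bytree`, `nrounds`.
#'
#' @param family `"plsr"`, `"svr"`, `"mlp"`, `"cnn"`, or `"gboost"`.
#' @param ... Family hyperparameters (see above). Unknown names are an
#'   error.
#' @param seed Integer seed for the stochastic solvers.
#' @return Object of class `thz_model_spec`.
#' @export
model_spec <- function(family = c("plsr", "svr", "mlp", "cnn", "gboost"),
                       ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    plsr = list(ncomp = 3L, prescale = FALSE),
    svr = list(nu = 0.5, cost = 1.0, gamma = "auto", kernel = "radial"),
    mlp = list(hidden = 4L, activation = "logistic",
               out_activation = "identity", alpha = 1e-4, maxit = 400L),
    cnn = list(filters = 8L, kernel = 16L, stride = 8L, epochs = 300L,
               lr = 0.01),
    gboost = list(eta = 0.01, max_depth = 5L, min_child_weight = 2,
                  gamma = 0, subsample = 0.3, colsample_bytree = 0.6,
                  nrounds = 500L))
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unsupported hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, user)
  if (family == "plsr" && params$ncomp < 1) stop("plsr needs ncomp >= 1")
  if (family == "svr" && (params$nu <= 0 || params$nu > 1))
    stop("svr nu must be in (0, 1]")
  if (family == "mlp") {
    params$activation <- match.arg(params$activation,
                                   c("logistic", "tanh", "identity"))
    params$out_activation <- match.arg(params$out_activation,
                                       c("identity", "tanh"))
  }
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "thz_model_spec")
}

#' Named model presets
#'
#' The `*-table2` presets carry the optimal hyperparameters reported for
#' each family in the source experiment's model comparison: PLSR with
#' prescale and 3 components; NuSVR with nu 0.5, C 1.0, rbf kernel, gamma
#' auto; MLP with 4 logistic neurons and the lbfgs solver; a sigmoid
#' residual-block CNN; gradient boosting with learning rate 0.01, max
#' depth 5, min child weight 2, gamma 0, subsample 0.3, colsample_bytree
#' 0.6. The reported 10,000 boosting rounds are scaled to 500 by default
#' for desk-scale runs (`gboost-table2-full` keeps the original count).
#' `mlp-tanh` / `mlp-linear` are the nonlinear and linear variants of the
#' linearity study (tanh vs identity activation in hidden and output
#' layers).
#'
#' @param name Preset name.
#' @param seed Seed recorded in the spec.
#' @return A [model_spec()].
#' @export
model_preset <- function(name = c("plsr-table2", "svr-table2", "mlp-table2",
                                  "mlp-linear", "mlp-tanh", "cnn-table2",
                                  "gboost-table2", "gboost-table2-full"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "plsr-table2" = model_spec("plsr", ncomp = 3, prescale = TRUE, seed = seed),
    "svr-table2" = model_spec("svr", nu = 0.5, cost = 1.0, gamma = "auto",
                              kernel = "radial", seed = seed),
    "mlp-table2" = model_spec("mlp", hidden = 4, activation = "logistic",
                              seed = seed),
    "mlp-linear" = model_spec("mlp", hidden = 8, activation = "identity",
                              out_activation = "identity", alpha = 1.0,
                              maxit = 2000L, seed = seed),
    "mlp-tanh" = model_spec("mlp", hidden = 8, activation = "tanh",
                            out_activation = "tanh", alpha = 1.0,
                            maxit = 2000L, seed = seed),
    "cnn-table2" = model_spec("cnn", seed = seed),
    "gboost-table2" = model_spec("gboost", seed = seed),
    "gboost-table2-full" = model_spec("gboost", nrounds = 10000L, seed = seed))
}

#' Train a calibration model
#'
#' @param spec A [model_spec()].
#' @param X Feature matrix (records x features), typically the reduced
#'   spectra.
#' @param Y Composition matrix (records x 3 mass ratios).
#' @return Object of class `thz_model`.
#' @export
train_model <- function(spec, X, Y) {
  stopifnot(inherits(spec, "thz_model_spec"))
  X <- unname(as.matrix(X)); Y <- unname(as.matrix(Y))
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("NaN/Inf in model inputs")
  p <- spec$params
  if (spec$family == "plsr" && nrow(X) < 2 * p$ncomp)
    stop("plsr needs >= 2 * ncomp training records")
  fit <- switch(spec$family,
    plsr = simpls_fit(X, Y, p$ncomp, p$prescale),
    svr = {
      gamma <- if (identical(p$gamma, "auto")) 1 / ncol(X) else p$gamma
      lapply(seq_len(ncol(Y)), function(j) {
        if (stats::sd(Y[, j]) == 0)      # degenerate target: no margin to fit
          return(list(constant = Y[1, j]))
        e1071::svm(x = X, y = Y[, j], type = "nu-regression", nu = p$nu,
                   cost = p$cost, gamma = gamma, kernel = p$kernel,
                   scale = FALSE)
      })
    },
    mlp = local_seed(spec$seed, mlp_fit(X, Y, p)),
    cnn = local_seed(spec$seed, cnn_fit(X, Y, p)),
    gboost = lapply(seq_len(ncol(Y)), function(j) {
      d <- xgboost::xgb.DMatrix(X, label = Y[, j])
      xgboost::xgb.train(params = list(eta = p$eta, max_depth = p$max_depth,
                                       min_child_weight = p$min_child_weight,
                                       gamma = p$gamma,
                                       subsample = p$subsample,
                                       colsample_bytree = p$colsample_bytree,
                                       nthread = 1,
                                       seed = spec$seed),
                         data = d, nrounds = p$nrounds, verbose = 0)
    }))
  structure(list(spec = spec, fit = fit, input_dim = ncol(X),
                 output_dim = ncol(Y),
                 per_output = spec$family %in% c("svr", "gboost")),
            class = "thz_model")
}

#' Predict compositions with a trained model
#'
#' Returns raw (unconstrained) predictions by default, matching how
#' calibration scatter is usually reported; `clip = TRUE` projects onto
#' `[0, 1]` post hoc.
#'
#' @param object A `thz_model`.
#' @param newdata Feature matrix with `input_dim` columns.
#' @param clip Clip predictions into `[0, 1]`?
#' @param ... Unused.
#' @return Matrix of predicted mass ratios (records x 3).
#' @export
predict.thz_model <- function(object, newdata, clip = FALSE, ...) {
  X <- unname(as.matrix(newdata))
  if (ncol(X) != object$input_dim)
    stop(sprintf("input has %d features; model expects %d",
                 ncol(X), object$input_dim))
  P <- switch(object$spec$family,
    plsr = simpls_predict(object$fit, X),
    svr = vapply(object$fit, function(m) {
      if (!is.null(m$constant)) rep(m$constant, nrow(X))
      else as.numeric(predict(m, X))
    }, numeric(nrow(X))),
    mlp = mlp_forward(object$fit, X)$yhat,
    cnn = cnn_forward(object$fit, X)$yhat,
    gboost = vapply(object$fit, function(m)
      predict(m, xgboost::xgb.DMatrix(X)), numeric(nrow(X))))
  P <- matrix(P, nrow = nrow(X))
  if (clip) P <- pmin(pmax(P, 0), 1)
  P
}

# ---- SIMPLS partial least squares (multi-response) -----------------------
simpls_fit <- function(X, Y, ncomp, prescale = FALSE) {
  xmean <- colMeans(X)
  xsd <- if (prescale) {
    s <- apply(X, 2, stats::sd); ifelse(s > 0, s, 1)
  } else rep(1, ncol(X))
  ymean <- colMeans(Y)
  Xc <- sweep(sweep(X, 2, xmean), 2, xsd, "/")
  Yc <- sweep(Y, 2, ymean)
  p <- ncol(X); q <- ncol(Y)
  R <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp); V <- matrix(0, p, ncomp)
  S <- crossprod(Xc, Yc)
  s0 <- sqrt(sum(S^2))
  used <- 0
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(S^2)) <= 1e-10 * s0) break  # covariance exhausted
    qa <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% qa
    t_ <- Xc %*% r
    t_ <- t_ - mean(t_)
    normt <- sqrt(sum(t_^2))
    if (a == 1) normt0 <- normt
    if (normt <= 1e-10 * normt0) break       # residual rank exhausted
    t_ <- t_ / normt; r <- r / normt
    pvec <- crossprod(Xc, t_)
    qvec <- crossprod(Yc, t_)
    v <- pvec
    if (a > 1) {
      Vu <- V[, seq_len(used), drop = FALSE]
      v <- v - Vu %*% crossprod(Vu, pvec)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- qvec; V[, a] <- v
    used <- a
  }
  R <- R[, seq_len(used), drop = FALSE]
  Q <- Q[, seq_len(used), drop = FALSE]
  B <- R %*% t(Q)
  list(B = B, xmean = xmean, xsd = xsd, ymean = ymean, ncomp_used = used)
}

simpls_predict <- function(fit, X) {
  Xc <- sweep(sweep(X, 2, fit$xmean), 2, fit$xsd, "/")
  sweep(Xc %*% fit$B, 2, fit$ymean, "+")
}

# ---- single-hidden-layer MLP trained with L-BFGS -------------------------
act_fun <- function(name) switch(name,
  logistic = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(a) a * (1 - a)),
  tanh = list(f = tanh, df = function(a) 1 - a^2),
  identity = list(f = identity, df = function(a) rep(1, length(a))))

mlp_fit <- function(X, Y, p) {
  n <- nrow(X); d <- ncol(X); h <- p$hidden; q <- ncol(Y)
  # standardize inputs internally for conditioning; part of the model state
  xmean <- colMeans(X)
  xsd <- apply(X, 2, stats::sd); xsd <- ifelse(xsd > 0, xsd, 1)
  Xs <- sweep(sweep(X, 2, xmean), 2, xsd, "/")
  npar <- d * h + h + h * q + q
  unpack <- function(theta) list(
    W1 = matrix(theta[seq_len(d * h)], d, h),
    b1 = theta[d * h + seq_len(h)],
    W2 = matrix(theta[d * h + h + seq_len(h * q)], h, q),
    b2 = theta[d * h + h + h * q + seq_len(q)])
  a1 <- act_fun(p$activation); a2 <- act_fun(p$out_activation)
  fwd <- function(w) {
    Z1 <- sweep(Xs %*% w$W1, 2, w$b1, "+")
    A1 <- a1$f(Z1)
    Z2 <- sweep(A1 %*% w$W2, 2, w$b2, "+")
    A2 <- a2$f(Z2)
    list(A1 = A1, A2 = A2)
  }
  obj <- function(theta) {
    w <- unpack(theta)
    f <- fwd(w)
    r <- f$A2 - Y
    0.5 * sum(r^2) / n +
      0.5 * p$alpha * (sum(w$W1^2) + sum(w$W2^2)) / n
  }
  grad <- function(theta) {
    w <- unpack(theta)
    f <- fwd(w)
    r <- f$A2 - Y
    d2 <- r * matrix(a2$df(f$A2), n, ncol(Y))          # n x q
    gW2 <- (crossprod(f$A1, d2) + p$alpha * w$W2) / n
    gb2 <- colSums(d2) / n
    d1 <- (d2 %*% t(w$W2)) * matrix(a1$df(f$A1), n, h)  # n x h
    gW1 <- (crossprod(Xs, d1) + p$alpha * w$W1) / n
    gb1 <- colSums(d1) / n
    c(as.vector(gW1), gb1, as.vector(gW2), gb2)
  }
  # sklearn-style scaled uniform init
  lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + q))
  theta0 <- c(stats::runif(d * h, -lim1, lim1), rep(0, h),
              stats::runif(h * q, -lim2, lim2), rep(0, q))
  opt <- stats::optim(theta0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = p$maxit))
  w <- unpack(opt$par)
  c(w, list(xmean = xmean, xsd = xsd, activation = p$activation,
            out_activation = p$out_activation, value = opt$value,
            convergence = opt$convergence))
}

mlp_forward <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$xmean), 2, fit$xsd, "/")
  a1 <- act_fun(fit$activation); a2 <- act_fun(fit$out_activation)
  A1 <- a1$f(sweep(Xs %*% fit$W1, 2, fit$b1, "+"))
  Z2 <- sweep(A1 %*% fit$W2, 2, fit$b2, "+")
  list(yhat = matrix(a2$f(Z2), nrow(X)))
}

# ---- minimal 1-D CNN with one residual block -----------------------------
# conv(width kernel, stride) -> sigmoid -> 1x1 conv + skip -> sigmoid
# -> global average pool -> dense; trained full-batch with Adam
cnn_patches <- function(p_in, kernel, stride) {
  starts <- seq(1, p_in - kernel + 1, by = stride)
  lapply(starts, function(s) s:(s + kernel - 1))
}

cnn_fit <- function(X, Y, p) {
  n <- nrow(X); d <- ncol(X); q <- ncol(Y)
  kernel <- min(p$kernel, d); stride <- max(1, min(p$stride, kernel))
  F <- p$filters
  patches <- cnn_patches(d, kernel, stride)
  P <- length(patches)
  xmean <- colMeans(X); xsd <- apply(X, 2, stats::sd)
  xsd <- ifelse(xsd > 0, xsd, 1)
  Xs <- sweep(sweep(X, 2, xmean), 2, xsd, "/")
  Xcol <- do.call(cbind, lapply(patches, function(ii) Xs[, ii, drop = FALSE]))
  # parameters
  W1 <- matrix(stats::rnorm(kernel * F, sd = sqrt(2 / kernel)), kernel, F)
  b1 <- rep(0, F)
  W2 <- matrix(stats::rnorm(F * F, sd = sqrt(2 / F)), F, F)
  b2 <- rep(0, F)
  Wd <- matrix(stats::rnorm(F * q, sd = sqrt(2 / F)), F, q)
  bd <- colMeans(Y)
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, Wd = Wd, bd = bd)
  mom <- lapply(pars, function(x) x * 0)
  vel <- lapply(pars, function(x) x * 0)
  sig <- function(z) 1 / (1 + exp(-z))
  fwd_full <- function(pr) {
    # H1[n, P, F] computed as a list over filter dim using matrix algebra
    H1 <- array(0, c(n, P, F))
    for (j in seq_len(P)) {
      blk <- Xcol[, ((j - 1) * kernel + 1):(j * kernel), drop = FALSE]
      H1[, j, ] <- blk %*% pr$W1
    }
    H1 <- sweep(H1, 3, pr$b1, "+")
    A1 <- sig(H1)
    H2 <- array(0, c(n, P, F))
    for (j in seq_len(P))
      H2[, j, ] <- A1[, j, ] %*% pr$W2
    H2 <- sweep(H2, 3, pr$b2, "+") + H1      # residual skip
    A2 <- sig(H2)
    pool <- apply(A2, c(1, 3), mean)          # n x F
    yhat <- sweep(pool %*% pr$Wd, 2, pr$bd, "+")
    list(A1 = A1, A2 = A2, H1 = H1, pool = pool, yhat = yhat)
  }
  for (epoch in seq_len(p$epochs)) {
    f <- fwd_full(pars)
    r <- (f$yhat - Y) / n                     # n x q
    g <- list()
    g$Wd <- crossprod(f$pool, r); g$bd <- colSums(r)
    dpool <- r %*% t(pars$Wd)                 # n x F
    dA2 <- array(rep(dpool / P, each = 1), c(n, F, P))
    dA2 <- aperm(dA2, c(1, 3, 2))             # n x P x F
    dH2 <- dA2 * f$A2 * (1 - f$A2)
    g$b2 <- apply(dH2, 3, sum)
    g$W2 <- matrix(0, F, F)
    dA1 <- array(0, c(n, P, F))
    for (j in seq_len(P)) {
      g$W2 <- g$W2 + crossprod(f$A1[, j, ], dH2[, j, ])
      dA1[, j, ] <- dH2[, j, ] %*% t(pars$W2)
    }
    dH1 <- dA1 * f$A1 * (1 - f$A1) + dH2      # skip path adds dH2 directly
    g$b1 <- apply(dH1, 3, sum)
    g$W1 <- matrix(0, kernel, F)
    for (j in seq_len(P)) {
      blk <- Xcol[, ((j - 1) * kernel + 1):(j * kernel), drop = FALSE]
      g$W1 <- g$W1 + crossprod(blk, dH1[, j, ])
    }
    # Adam
    b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
    for (nm in names(pars)) {
      mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * g[[nm]]
      vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1a^epoch)
      vhat <- vel[[nm]] / (1 - b2a^epoch)
      pars[[nm]] <- pars[[nm]] - p$lr * mhat / (sqrt(vhat) + eps)
    }
  }
  c(pars, list(kernel = kernel, stride = stride, filters = F,
               xmean = xmean, xsd = xsd, d = d, q = q))
}

cnn_forward <- function(fit, X) {
  n <- nrow(X)
  Xs <- sweep(sweep(X, 2, fit$xmean), 2, fit$xsd, "/")
  patches <- cnn_patches(fit$d, fit$kernel, fit$stride)
  P <- length(patches)
  sig <- function(z) 1 / (1 + exp(-z))
  F <- fit$filters
  H1 <- array(0, c(n, P, F))
  for (j in seq_len(P))
    H1[, j, ] <- Xs[, patches[[j]], drop = FALSE] %*% fit$W1
  H1 <- sweep(H1, 3, fit$b1, "+")
  A1 <- sig(H1)
  H2 <- array(0, c(n, P, F))
  for (j in seq_len(P))
    H2[, j, ] <- A1[, j, ] %*% fit$W2
  H2 <- sweep(H2, 3, fit$b2, "+") + H1
  A2 <- sig(H2)
  pool <- apply(A2, c(1, 3), mean)
  list(yhat = sweep(pool %*% fit$Wd, 2, fit$bd, "+"))
}
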