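#' Fit a per-feature normalizer on training spectra
#'
#' `"zscore"` centers each feature to mean 0 and scales to SD 1 on the
#' training block; `"minmax"` maps the training range of each feature to
#' `[0, 1]`. Statistics are learned from the training block only and then
#' applied unchanged to held-out spectra (held-out values may leave
#' `[0, 1]`). Degenerate features (zero SD / zero range) are mapped to 0 by
#' convention. Mie baseline removal is a dataset-level operation handled by
#' [remove_baseline()], not a per-feature transform.
#'
#' @param X Training matrix (records x features).
#' @param method `"zscore"`, `"minmax"`, or `"none"`.
#' @return Object of class `thz_normalizer`.
#' @export
fit_normalizer <- function(X, method = c("zscore", "minmax", "none")) {
  if (identical(method, "mie"))
    stop("Mie baseline removal is handled by remove_baseline(), not fit_normalizer()")
  method <- match.arg(method)
  X <- as.matrix(X)
  st <- switch(method,
    zscore = {
      if (nrow(X) < 2) stop("zscore needs >= 2 training spectra")
      mu <- colMeans(X)
      sd <- apply(X, 2, stats::sd)
      list(mu = mu, sd = sd)
    },
    minmax = {
      lo <- apply(X, 2, min)
      hi <- apply(X, 2, max)
      list(lo = lo, hi = hi)
    },
    none = list())
  structure(list(method = method, stats = st, p = ncol(X)),
            class = "thz_normalizer")
}

#' @rdname fit_normalizer
#' @param state A fitted `thz_normalizer`.
#' @export
apply_normalizer <- function(state, X) {
  stopifnot(inherits(state, "thz_normalizer"))
  X <- as.matrix(X)
  if (state$method == "none") return(X)
  if (ncol(X) != state$p) stop("feature count does not match the fitted state")
  if (state$method == "zscore") {
    sd <- state$stats$sd
    Z <- sweep(X, 2, state$stats$mu)
    Z <- sweep(Z, 2, ifelse(sd > 0, sd, 1), "/")
    Z[, sd == 0] <- 0
    return(Z)
  }
  rng <- state$stats$hi - state$stats$lo
  Z <- sweep(X, 2, state$stats$lo)
  Z <- sweep(Z, 2, ifelse(rng > 0, rng, 1), "/")
  Z[, rng == 0] <- 0
  Z
}

#' Declare a dimensionality-reduction stage
#'
#' @param method One of `"pca"`, `"fa"`, `"ica"`, `"lle"`, `"modified_lle"`,
#'   `"nmf"`, `"isomap"`, `"none"`.
#' @param n_components Embedding dimension.
#' @param n_neighbors Neighborhood size for `lle`, `modified_lle`, `isomap`.
#' @param concat_xi If TRUE, [apply_reducer()] appends the per-spectrum Mie
#'   coefficient as one extra feature after reduction.
#' @param seed Seed for the randomized solvers (ica, nmf); recorded in the
#'   fitted state.
#' @return Object of class `thz_reducer_spec`.
#' @export
reducer_spec <- function(method = c("none", "pca", "fa", "ica", "lle",
                                    "modified_lle", "nmf", "isomap"),
                         n_components = NULL, n_neighbors = NULL,
                         concat_xi = FALSE, seed = 1L) {
  method <- match.arg(method)
  if (method != "none") {
    stopifnot(!is.null(n_components), n_components >= 1)
    if (method %in% c("lle", "modified_lle", "isomap")) {
      if (is.null(n_neighbors)) n_neighbors <- max(10L, n_components + 1L)
      if (method %in% c("lle", "modified_lle") &&
          n_neighbors < n_components + 1)
        stop("n_neighbors must be >= n_components + 1 for LLE variants")
    }
  }
  structure(list(method = method,
                 n_components = if (!is.null(n_components)) as.integer(n_components),
                 n_neighbors = if (!is.null(n_neighbors)) as.integer(n_neighbors),
                 concat_xi = isTRUE(concat_xi), seed = as.integer(seed)),
            class = "thz_reducer_spec")
}

#' Fit a dimensionality reducer on a training matrix
#'
#' All reducers are fitted on the training block only; held-out data are
#' transformed with the fitted state (for LLE variants via neighbor-weight
#' reconstruction, for isomap via the landmark/Nystrom embedding formula).
#' Randomized solvers draw from the seed recorded in the spec, leaving the
#' global RNG untouched.
#'
#' @param X Training matrix (records x features).
#' @param spec A [reducer_spec()].
#' @return Object of class `thz_reducer` holding the fitted transform state.
#' @export
fit_reducer <- function(X, spec) {
  stopifnot(inherits(spec, "thz_reducer_spec"))
  X <- as.matrix(X)
  k <- spec$n_components
  if (spec$method != "none" && k > min(dim(X)))
    stop("n_components must be <= min(n_samples, n_features)")
  fit <- switch(spec$method,
    none = list(),
    pca = {
      pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
      list(center = pr$center, rotation = pr$rotation[, seq_len(k), drop = FALSE],
           sdev = pr$sdev)
    },
    fa = fa_fit(X, k),
    ica = local_seed(spec$seed, ica_fit(X, k)),
    nmf = local_seed(spec$seed, nmf_fit(X, k)),
    lle = lle_fit(X, k, spec$n_neighbors, modified = FALSE),
    modified_lle = lle_fit(X, k, spec$n_neighbors, modified = TRUE),
    isomap = isomap_fit(X, k, spec$n_neighbors))
  structure(list(spec = spec, fit = fit, p = ncol(X), n_train = nrow(X)),
            class = "thz_reducer")
}

#' Transform data with a fitted reducer
#'
#' @param state A fitted `thz_reducer`.
#' @param X Matrix to transform (training or held-out).
#' @param xi Per-record Mie coefficients, required iff the spec has
#'   `concat_xi = TRUE`; appended as the last output column.
#' @return Reduced matrix with `n_components` columns (+1 when `concat_xi`).
#' @export
apply_reducer <- function(state, X, xi = NULL) {
  stopifnot(inherits(state, "thz_reducer"))
  X <- as.matrix(X)
  if (state$spec$method != "none" && ncol(X) != state$p)
    stop("feature count does not match the fitted state")
  Z <- switch(state$spec$method,
    none = X,
    pca = sweep(X, 2, state$fit$center) %*% state$fit$rotation,
    fa = fa_transform(state$fit, X),
    ica = sweep(X, 2, state$fit$center) %*% state$fit$unmixing,
    nmf = nmf_transform(state$fit, X),
    lle = ,
    modified_lle = lle_transform(state$fit, X),
    isomap = isomap_transform(state$fit, X))
  if (state$spec$concat_xi) {
    if (is.null(xi)) stop("concat_xi reducer needs the per-record xi values")
    if (length(xi) != nrow(X)) stop("xi length must equal the record count")
    Z <- cbind(Z, xi)
  }
  unname(as.matrix(Z))
}

# ---- factor analysis via EM (diagonal-noise linear Gaussian model) -------
fa_fit <- function(X, k, max_iter = 200, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cov_diag <- colMeans(Xc^2)
  sv <- svd(Xc / sqrt(n), nu = 0, nv = k)
  L <- sv$v %*% diag(sv$d[seq_len(k)], k)   # PCA init for the loadings
  psi <- pmax(cov_diag - rowSums(L^2), 1e-8)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step via Woodbury on (L L' + Psi)^{-1}
    Lp <- L / psi
    Mk <- diag(k) + crossprod(L, Lp)        # I + L' Psi^-1 L
    Mki <- solve(Mk)
    B <- Lp %*% Mki                         # Psi^-1 L (I + L'Psi^-1 L)^-1
    Ez <- Xc %*% B                          # n x k posterior means
    Ezz <- Mki + crossprod(Ez) / n          # E[zz'] averaged
    # M-step
    Cxz <- crossprod(Xc, Ez) / n
    L <- Cxz %*% solve(Ezz)
    psi <- pmax(cov_diag - rowSums(L * Cxz), 1e-8)
    # monitored log-likelihood (up to constants)
    ld <- sum(log(psi)) + determinant(Mk, logarithm = TRUE)$modulus
    tr <- sum(Xc^2 %*% (1 / psi)) / n - sum((Xc %*% Lp) * (Xc %*% B)) / n
    ll <- -0.5 * (as.numeric(ld) + tr)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(mu = mu, loadings = L, psi = psi)
}

fa_transform <- function(fit, X) {
  Xc <- sweep(X, 2, fit$mu)
  Lp <- fit$loadings / fit$psi
  Mk <- diag(ncol(fit$loadings)) + crossprod(fit$loadings, Lp)
  Xc %*% (Lp %*% solve(Mk))
}

# ---- FastICA (symmetric decorrelation, logcosh nonlinearity) -------------
ica_fit <- function(X, k, max_iter = 300, tol = 1e-7) {
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0, nv = min(dim(Xc)))
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-12 * sv$d[1]))
    stop("data rank is below n_components; reduce n_components for ica")
  K <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sqrt(n) / d, k)  # whitening
  Z <- Xc %*% K                              # n x k, unit covariance
  W <- matrix(stats::rnorm(k * k), k)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% W                            # n x k
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- crossprod(Z, G) / n - sweep(W, 2, colMeans(Gp), "*")
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  list(center = center, unmixing = K %*% W)
}

# ---- NMF (Lee-Seung multiplicative updates, Frobenius loss) --------------
nmf_fit <- function(X, k, max_iter = 400, tol = 1e-6) {
  if (any(X < 0))
    stop("nmf requires non-negative inputs; apply min-max scaling or Mie baseline removal first")
  n <- nrow(X); p <- ncol(X)
  eps <- 1e-12
  H <- matrix(stats::runif(n * k, 0.1, 1) * sqrt(mean(X) / k), n)
  W <- matrix(stats::runif(k * p, 0.1, 1) * sqrt(mean(X) / k), k)
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (X %*% t(W)) / (H %*% W %*% t(W) + eps)
    W <- W * (t(H) %*% X) / (t(H) %*% H %*% W + eps)
    if (it %% 20 == 0) {
      err <- sum((X - H %*% W)^2)
      if (is.finite(err_old) && err_old - err < tol * err_old) break
      err_old <- err
    }
  }
  list(W = W)
}

nmf_transform <- function(fit, X, max_iter = 200) {
  if (any(X < 0)) {
    n_neg <- sum(X < 0)
    warning(sprintf("nmf transform: clipped %d negative value(s) at 0", n_neg))
    X <- pmax(X, 0)
  }
  W <- fit$W; k <- nrow(W); eps <- 1e-12
  H <- matrix(mean(X) / k, nrow(X), k) + eps
  WWt <- W %*% t(W)
  XWt <- X %*% t(W)
  for (it in seq_len(max_iter))
    H <- H * XWt / (H %*% WWt + eps)
  H
}

# ---- LLE and modified LLE ------------------------------------------------
knn_index <- function(D, k) {
  t(apply(D, 1, function(d) order(d)[2:(k + 1)]))   # skip self (position 1)
}

lle_fit <- function(X, k, n_neighbors, modified = FALSE, reg = 1e-3) {
  n <- nrow(X)
  if (n_neighbors >= n) stop("n_neighbors must be < number of training records")
  D <- as.matrix(stats::dist(X))
  NN <- knn_index(D, n_neighbors)
  Wmat <- matrix(0, n, n)
  if (!modified) {
    for (i in seq_len(n)) {
      Wmat[i, NN[i, ]] <- lle_weights(X[i, ], X[NN[i, ], , drop = FALSE], reg)
    }
    M <- crossprod(diag(n) - Wmat)
  } else {
    # modified LLE (multiple locally orthogonal weight vectors per point):
    # bottom eigenvectors of each local Gram matrix, aligned by a
    # Householder reflection and blended with the regularized single
    # weight vector
    nk <- n_neighbors
    Vlist <- vector("list", n)
    evmat <- matrix(0, n, nk)
    wreg <- matrix(0, n, nk)
    for (i in seq_len(n)) {
      Gi <- sweep(X[NN[i, ], , drop = FALSE], 2, X[i, ])
      C <- Gi %*% t(Gi)
      e <- eigen((C + t(C)) / 2, symmetric = TRUE)   # eigenvalues descending
      Vlist[[i]] <- e$vectors
      evmat[i, ] <- pmax(e$values, 0)
      Cr <- C + diag(nk) * reg * max(sum(diag(C)), 1e-300)
      w <- solve(Cr, rep(1, nk))
      wreg[i, ] <- w / sum(w)
    }
    rho <- rowSums(evmat[, (k + 1):nk, drop = FALSE]) /
      pmax(rowSums(evmat[, 1:k, drop = FALSE]), 1e-300)
    eta <- stats::median(rho)
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      ev <- evmat[i, ]
      # s_i = largest trailing set with (tail sum)/(head sum) < eta
      cs <- cumsum(ev)
      tail_ratio <- (cs[nk] - cs[seq_len(nk - 1)]) /
        pmax(cs[seq_len(nk - 1)], 1e-300)
      s_i <- sum(tail_ratio < eta)
      s_i <- min(max(s_i, 1L), nk - k)
      Vi <- Vlist[[i]][, (nk - s_i + 1):nk, drop = FALSE]
      alpha_i <- norm(colSums(Vi), "2") / sqrt(s_i)
      h <- alpha_i - as.vector(crossprod(Vi, rep(1, nk)))
      nh <- norm(h, "2")
      h <- if (nh < 1e-12) h * 0 else h / nh
      Wi <- Vi - 2 * (Vi %*% h) %*% t(h) +
        (1 - alpha_i) * wreg[i, ]            # nk x s_i
      What <- matrix(0, n, s_i)
      What[NN[i, ], ] <- Wi
      What[i, ] <- What[i, ] - 1
      M <- M + tcrossprod(What)
    }
  }
  emb <- bottom_eigenvectors(M, k)
  list(X = X, NN = NN, weights = if (!modified) Wmat, embedding = emb,
       n_neighbors = n_neighbors, reg = reg, k = k)
}

lle_weights <- function(x, neighbors, reg) {
  Gi <- sweep(neighbors, 2, x)
  C <- Gi %*% t(Gi)
  C <- C + diag(nrow(C)) * reg * max(sum(diag(C)), 1e-300)
  w <- solve(C, rep(1, nrow(C)))
  w / sum(w)
}

bottom_eigenvectors <- function(M, k) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n <- ncol(M)
  # discard the constant eigenvector (smallest eigenvalue), take next k
  idx <- order(e$values)[2:(k + 1)]
  emb <- e$vectors[, idx, drop = FALSE] * sqrt(n)
  emb
}

lle_transform <- function(fit, X) {
  if (nrow(X) == nrow(fit$X) && isTRUE(all.equal(unname(X), unname(fit$X),
                                                 tolerance = 0)))
    return(fit$embedding)
  # out-of-sample: reconstruct each new point from its training neighbors
  n_new <- nrow(X)
  Z <- matrix(0, n_new, ncol(fit$embedding))
  for (i in seq_len(n_new)) {
    d <- colSums((t(fit$X) - X[i, ])^2)
    nn <- order(d)[seq_len(fit$n_neighbors)]
    w <- lle_weights(X[i, ], fit$X[nn, , drop = FALSE], fit$reg)
    Z[i, ] <- w %*% fit$embedding[nn, , drop = FALSE]
  }
  Z
}

# ---- isomap --------------------------------------------------------------
isomap_fit <- function(X, k, n_neighbors) {
  n <- nrow(X)
  if (n_neighbors >= n) stop("n_neighbors must be < number of training records")
  D <- as.matrix(stats::dist(X))
  NN <- knn_index(D, n_neighbors)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, NN[i, ]] <- D[i, NN[i, ]]
  A <- pmax(A, t(A))                         # symmetrize the kNN graph
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  G <- igraph::distances(g)
  if (any(!is.finite(G)))
    stop("kNN graph is disconnected; increase n_neighbors")
  G2 <- G^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% G2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  if (any(vals <= 0))
    stop("isomap: fewer than n_components positive eigenvalues")
  emb <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  list(X = X, G = G, NN = NN, evals = vals,
       evecs = e$vectors[, seq_len(k), drop = FALSE],
       col_mean_sq = colMeans(G2), embedding = emb,
       n_neighbors = n_neighbors)
}

isomap_transform <- function(fit, X) {
  if (nrow(X) == nrow(fit$X) && isTRUE(all.equal(unname(X), unname(fit$X),
                                                 tolerance = 0)))
    return(fit$embedding)
  n <- nrow(fit$X); n_new <- nrow(X)
  Z <- matrix(0, n_new, length(fit$evals))
  for (i in seq_len(n_new)) {
    d <- sqrt(colSums((t(fit$X) - X[i, ])^2))
    nn <- order(d)[seq_len(fit$n_neighbors)]
    # geodesic distance from the new point through its anchor neighbors
    gd <- apply(fit$G[nn, , drop = FALSE] + d[nn], 2, min)
    # landmark (Nystrom) embedding
    Z[i, ] <- colSums(fit$evecs * (fit$col_mean_sq - gd^2)) /
      (2 * sqrt(fit$evals))
  }
  Z
}
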