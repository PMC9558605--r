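#' Physical parameters of the Mie scatterer
#'
#' The pellet binder is a high-density polyethylene powder; its grains
#' scatter the THz beam approximately as homogeneous spheres, producing a
#' rising broadband baseline proportional to the extinction efficiency
#' Qext. HDPE is nearly lossless and has refractive index about 1.54 in the
#' THz band; the default 30 micrometer radius is a typical powder grain
#' scale. Both defaults are modeling choices and should be overridden when
#' the grain-size distribution is known; they are recorded in every
#' baseline fit.
#'
#' @param radius_um Sphere radius in micrometers (> 0).
#' @param ref_index Complex refractive index of the sphere.
#' @param medium_index Real refractive index of the surrounding medium.
#' @return Object of class `thz_mie_params`.
#' @export
mie_params <- function(radius_um = 30, ref_index = 1.54 + 0i,
                       medium_index = 1.0) {
  if (radius_um <= 0) stop("particle radius must be > 0")
  if (Re(ref_index) <= 0) stop("real part of the refractive index must be > 0")
  structure(list(radius_um = radius_um, ref_index = as.complex(ref_index),
                 medium_index = medium_index),
            class = "thz_mie_params")
}

#' Mie extinction efficiency on a frequency grid
#'
#' Evaluates Qext for a homogeneous sphere at each grid frequency from the
#' Mie series: size parameter `x = 2 pi r f n_medium / c`, coefficients
#' `a_n`, `b_n` from the logarithmic-derivative downward recurrence and
#' Riccati-Bessel upward recurrences, truncated at
#' `N = ceil(x + 4 x^(1/3) + 2)`, and
#' `Qext = (2/x^2) sum (2n+1) Re(a_n + b_n)`.
#'
#' @param params A [mie_params()].
#' @param grid A [thz_grid()] or numeric frequency vector (THz).
#' @return Numeric vector of Qext values, one per frequency; all finite and
#'   non-negative.
#' @export
mie_extinction_efficiency <- function(params, grid) {
  stopifnot(inherits(params, "thz_mie_params"))
  freqs <- if (inherits(grid, "thz_grid")) grid$frequencies else as.numeric(grid)
  if (any(freqs <= 0)) stop("frequencies must be positive")
  c_um_ps <- 299.792458   # speed of light in micrometers / picosecond
  x <- 2 * pi * params$radius_um * freqs * params$medium_index / c_um_ps
  m <- params$ref_index / params$medium_index
  q <- vapply(x, function(xi) mie_qext_one(m, xi), numeric(1))
  bad <- which(!is.finite(q))
  if (length(bad))
    stop(sprintf("Mie series did not converge at %.4g THz", freqs[bad[1]]))
  pmax(q, 0)
}

# Qext for one size parameter (Bohren-Huffman style recurrences)
mie_qext_one <- function(m, x) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  # downward recurrence for the logarithmic derivative D_n(mx)
  nstart <- max(nmax, ceiling(Mod(mx))) + 15
  D <- complex(nstart + 1)
  for (n in nstart:1)
    D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  # upward Riccati-Bessel: psi_n(x) = x j_n(x), chi_n(x) = -x y_n(x)
  psi_nm1 <- cos(x); psi_n <- sin(x)      # psi_{-1}, psi_0
  chi_nm1 <- -sin(x); chi_n <- cos(x)     # chi_{-1}, chi_0
  qsum <- 0
  for (n in 1:nmax) {
    psi_np <- (2 * n - 1) / x * psi_n - psi_nm1
    chi_np <- (2 * n - 1) / x * chi_n - chi_nm1
    xi_n <- complex(real = psi_np, imaginary = -chi_np)
    xi_nm1 <- complex(real = psi_n, imaginary = -chi_n)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a_n <- (da * psi_np - psi_n) / (da * xi_n - xi_nm1)
    b_n <- (db * psi_np - psi_n) / (db * xi_n - xi_nm1)
    qsum <- qsum + (2 * n + 1) * Re(a_n + b_n)
    psi_nm1 <- psi_n; psi_n <- psi_np
    chi_nm1 <- chi_n; chi_n <- chi_np
  }
  2 / x^2 * qsum
}

#' Valid-frequency mask for baseline fitting
#'
#' Marks the grid points used when fitting the scattering baseline: points
#' below the low-frequency cutoff (noisy, often negative absorbance) and
#' points within `halfwidth` of any water-vapor line are excluded. Bands
#' are closed intervals: an edge landing exactly on a grid point excludes
#' that point.
#'
#' @param grid A [thz_grid()].
#' @param water_lines Line positions (THz); default [thz_water_lines()].
#' @param halfwidth Exclusion half-width around each line (THz; 0.025 =
#'   25 GHz).
#' @param low_cut Two-element band (THz) excluded at the low-frequency end.
#' @return Object of class `thz_mask`: list with logical `mask` (TRUE =
#'   valid) and the defining parameters.
#' @export
valid_frequency_mask <- function(grid, water_lines = thz_water_lines(),
                                 halfwidth = 0.025, low_cut = c(0.3, 0.55)) {
  validate_grid(grid)
  if (halfwidth < 0) stop("halfwidth must be >= 0")
  f <- grid$frequencies
  ok <- f > low_cut[2]
  for (w in water_lines)
    ok <- ok & (f < w - halfwidth | f > w + halfwidth)
  if (!any(ok)) stop("valid frequency set is empty")
  structure(list(mask = ok, water_lines = water_lines,
                 exclusion_halfwidth = halfwidth, low_cut = low_cut),
            class = "thz_mask")
}

#' Fit the Mie baseline coefficient of one spectrum
#'
#' Finds the scalar `xi >= 0` scaling Qext into a baseline that hugs the
#' spectral troughs over the valid set Omega. Two equivalent routes are
#' provided. `"penalty"` minimizes the convex objective
#' `sum over Omega of (a - xi Qext) + M * sum over Omega of
#' max(0, xi Qext - a)`, with `M` a large constant keeping the baseline
#' from exceeding the troughs; the objective is piecewise linear in `xi`,
#' so the exact minimizer is found on the breakpoint set `{0, a_i/Q_i}`.
#' `"closed_form"` is its large-M limit, `xi = max(0, min over Omega of
#' a/Qext)`. A negative unconstrained optimum is clipped to 0 with a
#' warning.
#'
#' @param absorbance Numeric spectrum (one record).
#' @param qext Qext evaluated on the same grid.
#' @param mask A [valid_frequency_mask()].
#' @param penalty_M Penalty constant; default `1e6 * max(a) / min(Qext on
#'   Omega)`, large enough that both routes agree to 1e-6.
#' @param method `"penalty"` (default, mirrors the optimization as posed) or
#'   `"closed_form"`.
#' @return The fitted scalar `xi`.
#' @export
fit_baseline_coefficient <- function(absorbance, qext, mask,
                                     penalty_M = NULL,
                                     method = c("penalty", "closed_form")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "thz_mask"),
            length(absorbance) == length(mask$mask),
            length(qext) == length(mask$mask))
  if (any(!is.finite(absorbance))) stop("spectrum must be finite")
  a <- absorbance[mask$mask]
  q <- qext[mask$mask]
  keep <- q > 0
  if (!any(keep)) stop("Qext is zero everywhere on the valid set")
  a <- a[keep]; q <- q[keep]
  ratio_min <- min(a / q)
  if (method == "closed_form") {
    if (ratio_min < 0) {
      warning("negative optimal xi clipped to 0")
      return(0)
    }
    return(ratio_min)
  }
  if (is.null(penalty_M))
    penalty_M <- 1e6 * max(abs(a), 1e-12) / min(q)
  obj <- function(xi) {
    r <- a - xi * q
    sum(r) + penalty_M * sum(pmax(0, -r))
  }
  cand <- unique(c(0, pmax(0, a / q)))
  xi <- cand[which.min(vapply(cand, obj, numeric(1)))]
  if (ratio_min < 0 && xi == 0)
    warning("negative optimal xi clipped to 0")
  xi
}

#' Remove the Mie scattering baseline from datasets
#'
#' Subtracts `xi * Qext` from every spectrum over the full grid. Three
#' modes: `"multifactor"` fits and removes each spectrum's own `xi`
#' (training and apply sets alike); `"single_factor"` uses one shared
#' `xi`, the minimum over the training spectra, for every spectrum
#' including the apply set; `"multifactor_concat"` behaves as multifactor
#' and additionally returns the per-spectrum `xi` values so they can be
#' concatenated as an extra feature after dimensionality reduction.
#'
#' @param train A `thz_dataset` used to determine shared coefficients.
#' @param apply Optional second `thz_dataset` (e.g. a held-out fold) on the
#'   same grid.
#' @param params [mie_params()] defining Qext (ignored when `qext` given).
#' @param mask A [valid_frequency_mask()] on the shared grid.
#' @param mode One of `"multifactor"`, `"single_factor"`,
#'   `"multifactor_concat"`.
#' @param penalty_M,method Passed to [fit_baseline_coefficient()].
#' @param qext Optional precomputed Qext vector.
#' @return List with corrected datasets `train` and `apply`, coefficient
#'   vectors `xi_train` and `xi_apply` (in record order), the `mode`,
#'   `qext`, and `params`.
#' @export
remove_baseline <- function(train, apply = NULL, params = mie_params(),
                            mask, mode = c("multifactor", "single_factor",
                                           "multifactor_concat"),
                            penalty_M = NULL, method = "penalty",
                            qext = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "thz_dataset"))
  if (!is.null(apply) && !grids_identical(train$grid, apply$grid))
    stop("apply-set grid does not match the training grid")
  if (is.null(qext)) qext <- mie_extinction_efficiency(params, train$grid)
  fit_all <- function(ds) {
    n_clipped <- 0L
    out <- withCallingHandlers(
      vapply(seq_len(nrow(ds$absorbance)), function(i)
        fit_baseline_coefficient(ds$absorbance[i, ], qext, mask,
                                 penalty_M = penalty_M, method = method),
        numeric(1)),
      warning = function(w) {
        if (grepl("clipped", conditionMessage(w))) {
          n_clipped <<- n_clipped + 1L
          invokeRestart("muffleWarning")
        }
      })
    if (n_clipped > 0)
      warning(sprintf("negative optimal xi clipped to 0 for %d of %d spectra",
                      n_clipped, nrow(ds$absorbance)))
    out
  }
  xi_train <- fit_all(train)
  if (mode == "single_factor") {
    xi_shared <- min(xi_train)
    xi_train_use <- rep(xi_shared, length(xi_train))
    xi_apply_use <- if (!is.null(apply)) rep(xi_shared, nrow(apply$absorbance))
  } else {
    xi_train_use <- xi_train
    xi_apply_use <- if (!is.null(apply)) fit_all(apply)
  }
  correct <- function(ds, xi) {
    ds$absorbance <- ds$absorbance - outer(xi, qext)
    ds
  }
  list(train = correct(train, xi_train_use),
       apply = if (!is.null(apply)) correct(apply, xi_apply_use),
       xi_train = xi_train_use,
       xi_apply = xi_apply_use,
       mode = mode, qext = qext, params = params)
}
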