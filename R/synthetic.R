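#' Atmospheric water-vapor line positions in the THz band
#'
#' Strong rotational water lines between 0.3 and 3.0 THz, used both as the
#' default exclusion list for the baseline-fitting mask and as the default
#' positions of residual absorption artifacts in the generator (the
#' measurement chamber is nitrogen-purged, so artifacts are weak but
#' present). Values in THz, from standard line compilations.
#' @return Numeric vector of line frequencies (THz).
#' @export
thz_water_lines <- function() {
  c(0.557, 0.752, 0.988, 1.097, 1.113, 1.163, 1.207, 1.229, 1.411,
    1.602, 1.669, 1.717, 1.762, 1.797, 1.867, 1.919, 2.040, 2.074,
    2.164, 2.196, 2.245, 2.264, 2.344, 2.466, 2.554, 2.640, 2.685,
    2.773, 2.884, 2.970)
}

#' Absorption-peak library for the three analytes
#'
#' Each component is described by a set of (center, half-width, amplitude)
#' absorption peaks plus a broadband slope coefficient. Peaks are rendered
#' as compact-support (truncated) Lorentzians, so the spectra are exactly
#' zero away from resonances: the broadband background of a pellet spectrum
#' is attributed entirely to Mie scattering and modeled separately as
#' xi*Qext. All three default libraries leave a shared transparent window
#' near 1.26--1.40 THz. The default constants are placed in the
#' literature-reported feature ranges of the three compounds (distinct
#' fingerprints, strongest lines above 2 THz) but are documented modeling
#' constants, not measurements.
#'
#' @param peaks Named list (`caffeine`, `quinic_acid`, `nicotinic_acid`) of
#'   3-column matrices `(center_THz, halfwidth_THz, amplitude)`.
#' @param slope Named numeric: broadband slope coefficient per component
#'   (absorbance per THz above the band edge).
#' @return Object of class `thz_library`.
#' @export
component_library <- function(peaks, slope = NULL) {
  if (is.null(slope)) slope <- stats::setNames(rep(0, length(peaks)), names(peaks))
  stopifnot(setequal(names(peaks), analyte_names),
            setequal(names(slope), analyte_names))
  sig <- character(3)
  for (nm in analyte_names) {
    p <- peaks[[nm]] <- as.matrix(peaks[[nm]])
    if (ncol(p) != 3) stop("each peak matrix needs columns center, halfwidth, amplitude")
    if (any(p[, 2] <= 0)) stop("peak half-widths must be > 0")
    if (any(p[, 3] < 0)) stop("peak amplitudes must be >= 0")
    sig[match(nm, analyte_names)] <- paste(signif(c(t(p)), 10), collapse = ",")
  }
  if (anyDuplicated(sig))
    stop("component peak lists must be mutually distinguishable")
  structure(list(peaks = peaks[analyte_names], slope = slope[analyte_names]),
            class = "thz_library")
}

#' @rdname component_library
#' @export
default_component_library <- function() {
  component_library(peaks = list(
    caffeine = rbind(c(1.05, 0.025, 0.60),
                     c(1.65, 0.030, 0.90),
                     c(2.22, 0.030, 1.00),
                     c(2.62, 0.035, 0.70)),
    quinic_acid = rbind(c(0.90, 0.025, 0.50),
                        c(1.75, 0.030, 0.70),
                        c(2.05, 0.030, 0.90),
                        c(2.85, 0.030, 0.80)),
    nicotinic_acid = rbind(c(0.80, 0.025, 0.45),
                           c(1.95, 0.030, 0.80),
                           c(2.45, 0.030, 1.00),
                           c(2.95, 0.025, 0.60))))
}

# truncated Lorentzian: unit peak height, zero beyond `cut` half-widths
trunc_lorentz <- function(f, center, hw, cut = 8) {
  l <- hw^2 / ((f - center)^2 + hw^2)
  lcut <- 1 / (1 + cut^2)
  pmax(0, (l - lcut) / (1 - lcut))
}

#' Evaluate pure-component spectra on a grid
#' @param library A [component_library()].
#' @param grid A [thz_grid()].
#' @return 3 x p matrix of pure-component absorbance spectra (rows in
#'   analyte order).
#' @export
library_spectra <- function(library, grid) {
  stopifnot(inherits(library, "thz_library"))
  validate_grid(grid)
  f <- grid$frequencies
  fmin <- f[1] - grid$resolution
  S <- t(vapply(analyte_names, function(nm) {
    p <- library$peaks[[nm]]
    s <- rep(0, length(f))
    for (i in seq_len(nrow(p)))
      s <- s + p[i, 3] * trunc_lorentz(f, p[i, 1], p[i, 2])
    s + library$slope[[nm]] * (f - fmin)
  }, numeric(length(f))))
  rownames(S) <- analyte_names
  S
}

# smooth pairwise cross-term spectra for the nonlinear mixing departure:
# each interaction modulates the two partners' own absorption bands,
# g_cc' = (s_c + s_c')/2, derived deterministically from the library.
# Keeping the cross-terms inside the span of the component spectra is
# essential: interaction energy deposited in fresh spectral channels could
# be projected out by a linear readout, leaving the inverse map
# spectrum -> composition exactly linear and the departure undetectable.
# Modulating the partners' own bands makes the effective band amplitudes
# quadratic in the mass ratios, so inverting them is a genuinely
# nonlinear problem.
cross_term_spectra <- function(library, grid) {
  S <- library_spectra(library, grid)
  pairs <- utils::combn(analyte_names, 2)
  G <- matrix(0, ncol(pairs), ncol(S))
  for (j in seq_len(ncol(pairs)))
    G[j, ] <- (S[pairs[1, j], ] + S[pairs[2, j], ]) / 2
  rownames(G) <- apply(pairs, 2, paste, collapse = ":")
  G
}

#' Simulation configuration for the synthetic measurement campaign
#'
#' Defaults mirror the experimental design being emulated: 10 points on each
#' edge and median of the ternary diagram (60 systematic compositions), 20
#' random interior compositions, 6 replicate spectra per sample (480 spectra
#' total), replicate-level Gaussian noise, an additive Mie-scattering
#' baseline `xi*Qext` with `xi` drawn per replicate, pellet-thickness jitter
#' multiplying the chemical signal, compact water-line artifacts, and an
#' optional pairwise nonlinear mixing term.
#'
#' @param n_edge_points Points per simplex edge/median (default 10).
#' @param n_random Random interior compositions (default 20).
#' @param replicates Spectra per sample (default 6).
#' @param noise_sd SD of i.i.d. additive noise, absorbance units.
#' @param baseline_xi_range Range `(min, max)` of the per-replicate Mie
#'   coefficient `xi` (dimensionless); `c(0, 0)` disables the baseline.
#' @param thickness_jitter Relative SD of the per-replicate multiplicative
#'   thickness factor.
#' @param nonlinearity_strength Weight of the pairwise cross-term departure
#'   from linear (Beer-Lambert) mixing; 0 = exactly linear.
#' @param water_lines Artifact line positions (THz).
#' @param water_amplitude Peak amplitude of the line artifacts (absorbance).
#' @param mie [mie_params()] used to shape the scattering baseline.
#' @param seed Integer root seed; the whole campaign is reproducible from it.
#' @return Object of class `thz_sim_config`.
#' @export
sim_config <- function(n_edge_points = 10, n_random = 20, replicates = 6,
                       noise_sd = 0.01, baseline_xi_range = c(0.05, 0.3),
                       thickness_jitter = 0.03, nonlinearity_strength = 1.0,
                       water_lines = thz_water_lines()[c(3, 5, 9, 17, 23)],
                       water_amplitude = 0.08,
                       mie = mie_params(), seed = 42) {
  stopifnot(n_edge_points >= 1, n_random >= 0, replicates >= 1,
            noise_sd >= 0, length(baseline_xi_range) == 2,
            baseline_xi_range[1] >= 0,
            baseline_xi_range[2] >= baseline_xi_range[1],
            thickness_jitter >= 0, nonlinearity_strength >= 0,
            water_amplitude >= 0)
  structure(list(n_edge_points = as.integer(n_edge_points),
                 n_random = as.integer(n_random),
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd, baseline_xi_range = baseline_xi_range,
                 thickness_jitter = thickness_jitter,
                 nonlinearity_strength = nonlinearity_strength,
                 water_lines = water_lines,
                 water_amplitude = water_amplitude,
                 mie = mie, seed = as.integer(seed)),
            class = "thz_sim_config")
}

#' Mixture design on the ternary diagram
#'
#' Systematic part: `n_edge_points` points evenly spaced on each of the
#' three edges (parameter `t = k/n`, `k = 0..n-1`; the half-open
#' parameterization places each vertex exactly once across the edge cycle)
#' and on each of the three medians (vertex to opposite-edge midpoint,
#' interior points `t = k/(n+1)`, `k = 1..n`, which by construction misses
#' the centroid and the edge endpoints). With the default `n = 10` this
#' gives 60 unique compositions: 3 unitary, 27 binary, 30 ternary. Random
#' part: `n_random` points drawn uniformly on the open simplex interior.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `caffeine`, `quinic_acid`,
#'   `nicotinic_acid`, `tag` ("systematic"/"random"), `mixture_order`.
#' @export
design_compositions <- function(config = sim_config()) {
  n <- config$n_edge_points
  if (n < 2) stop("n_edge_points must be >= 2")
  v <- diag(3)
  pts <- list()
  for (e in 1:3) {            # edges v1->v2, v2->v3, v3->v1, t in [0, 1)
    a <- v[e, ]; b <- v[e %% 3 + 1, ]
    for (k in 0:(n - 1)) {
      t <- k / n
      pts[[length(pts) + 1]] <- (1 - t) * a + t * b
    }
  }
  for (m in 1:3) {            # medians: vertex -> opposite-edge midpoint
    a <- v[m, ]; b <- (v[m %% 3 + 1, ] + v[(m + 1) %% 3 + 1, ]) / 2
    for (k in 1:n) {
      t <- k / (n + 1)
      pts[[length(pts) + 1]] <- (1 - t) * a + t * b
    }
  }
  sys <- do.call(rbind, pts)
  rnd <- local_seed(config$seed, {
    if (config$n_random > 0) {
      e <- matrix(stats::rexp(3 * config$n_random), ncol = 3)
      e / rowSums(e)
    }
  })
  Y <- rbind(sys, rnd)
  key <- apply(round(Y, 12), 1, paste, collapse = "|")
  if (anyDuplicated(key))
    stop("duplicate design point(s): ",
         paste(utils::head(key[duplicated(key)], 5), collapse = "; "))
  data.frame(caffeine = Y[, 1], quinic_acid = Y[, 2], nicotinic_acid = Y[, 3],
             tag = rep(c("systematic", "random"),
                       c(nrow(sys), nrow(Y) - nrow(sys))),
             mixture_order = mixture_order(Y))
}

#' Simulate a replicated spectral dataset
#'
#' For each composition and replicate the spectrum is assembled as
#' `t_r * (y' S + strength * sum over pairs of y_c y_c' g_cc') +
#' xi_r * Qext + water artifacts + noise`, where `S` are the pure-component
#' spectra from the library, `g` the deterministic cross-term spectra,
#' `t_r` the per-replicate thickness factor, and `xi_r` a per-replicate
#' draw from `baseline_xi_range`. A chemical signal that goes negative
#' after mixing (possible with user-supplied slopes) is clipped at zero
#' with a warning; additive noise is never clipped, so slightly negative
#' absorbances at transparent frequencies occur just as in measurements.
#'
#' @param library A [component_library()].
#' @param compositions Data frame from [design_compositions()] (or any frame
#'   with the three analyte columns and optionally `tag`).
#' @param config A [sim_config()].
#' @param grid A [thz_grid()].
#' @return A `thz_dataset` with `nrow(compositions) * replicates` records.
#'   Attribute `xi_true` carries the injected per-record baseline
#'   coefficients; attribute `thickness` the thickness factors.
#' @export
simulate_dataset <- function(library = default_component_library(),
                             compositions = design_compositions(config),
                             config = sim_config(),
                             grid = thz_grid()) {
  stopifnot(inherits(config, "thz_sim_config"))
  validate_grid(grid)
  S <- library_spectra(library, grid)
  G <- cross_term_spectra(library, grid)
  f <- grid$frequencies
  qext <- mie_extinction_efficiency(config$mie, grid)
  art <- rep(0, length(f))
  for (w in config$water_lines)   # compact support: zero beyond +/- 25 GHz
    art <- art + trunc_gauss(f, w, 0.008, cut = 0.025)
  art <- config$water_amplitude * art
  Y <- as.matrix(compositions[, analyte_names])
  if (any(abs(rowSums(Y) - 1) > 1e-9)) stop("compositions must sum to 1")
  pair_idx <- utils::combn(3, 2)
  XT <- Y[, pair_idx[1, ], drop = FALSE] * Y[, pair_idx[2, ], drop = FALSE]
  chem <- Y %*% S + config$nonlinearity_strength * (XT %*% G)
  n_clip <- sum(chem < 0)
  if (n_clip > 0) {
    warning(sprintf("clipped %d negative chemical amplitude(s) at 0", n_clip))
    chem <- pmax(chem, 0)
  }
  n_s <- nrow(Y); R <- config$replicates
  n_rec <- n_s * R
  A <- matrix(0, n_rec, length(f))
  xi_true <- numeric(n_rec); thick <- numeric(n_rec)
  local_seed(config$seed, {
    for (i in seq_len(n_s)) {
      for (r in seq_len(R)) {
        row <- (i - 1) * R + r
        t_r <- max(0.1, 1 + stats::rnorm(1, sd = config$thickness_jitter))
        xi_r <- stats::runif(1, config$baseline_xi_range[1],
                             config$baseline_xi_range[2])
        eps <- if (config$noise_sd > 0)
          stats::rnorm(length(f), sd = config$noise_sd) else 0
        A[row, ] <- t_r * chem[i, ] + xi_r * qext + art + eps
        xi_true[row] <- xi_r; thick[row] <- t_r
      }
    }
  })
  tag <- if (!is.null(compositions$tag)) compositions$tag else NA_character_
  meta <- data.frame(sample_id = rep(sprintf("S%03d", seq_len(n_s)), each = R),
                     replicate = rep(seq_len(R), n_s),
                     caffeine = rep(Y[, 1], each = R),
                     quinic_acid = rep(Y[, 2], each = R),
                     nicotinic_acid = rep(Y[, 3], each = R),
                     tag = rep(tag, each = R))
  ds <- thz_dataset(grid, A, meta)
  attr(ds, "xi_true") <- xi_true
  attr(ds, "thickness") <- thick
  ds
}

# unit-height Gaussian truncated to zero beyond +/- cut (absolute units)
trunc_gauss <- function(f, center, sd, cut) {
  g <- exp(-(f - center)^2 / (2 * sd^2))
  gcut <- exp(-cut^2 / (2 * sd^2))
  pmax(0, (g - gcut) / (1 - gcut))
}

# evaluate an expression under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
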