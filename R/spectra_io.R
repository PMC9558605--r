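#' Mixture composition as dimensionless mass ratios
#'
#' The regression target: the mass of each analyte divided by the total
#' analyte mass (the polyethylene binder is excluded). Components must be
#' non-negative and sum to one.
#'
#' @param caffeine,quinic_acid,nicotinic_acid Mass ratios in `[0, 1]`.
#' @return Named numeric vector of length 3, class `thz_composition`.
#' @export
composition <- function(caffeine, quinic_acid, nicotinic_acid) {
  y <- c(caffeine = caffeine, quinic_acid = quinic_acid,
         nicotinic_acid = nicotinic_acid)
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1))
    stop("mass ratios must be finite and in [0, 1]")
  if (abs(sum(y) - 1) > 1e-9)
    stop(sprintf("mass ratios must sum to 1 (got %.12g)", sum(y)))
  structure(y, class = "thz_composition")
}

#' Number of nonzero components of a composition
#'
#' 1 = unitary (pure compound), 2 = binary, 3 = ternary mixture.
#' @param y Numeric vector or matrix (rows = compositions).
#' @return Integer vector of mixture orders.
#' @export
mixture_order <- function(y) {
  if (is.matrix(y)) return(as.integer(rowSums(y > 0)))
  as.integer(sum(y > 0))
}

analyte_names <- c("caffeine", "quinic_acid", "nicotinic_acid")

#' Assemble a spectra dataset
#'
#' The central container: an `n x p` absorbance matrix on a shared frequency
#' grid plus per-record metadata (sample id, replicate index, composition,
#' mixture order). All replicates of one sample share its composition, and
#' every sample must carry the same number of replicates.
#'
#' @param grid A [thz_grid()].
#' @param absorbance Numeric matrix, one row per record, `length(grid)` columns.
#' @param meta Data frame with columns `sample_id`, `replicate`, `caffeine`,
#'   `quinic_acid`, `nicotinic_acid`; optional `tag`. `mixture_order` is
#'   derived.
#' @return Object of class `thz_dataset`.
#' @export
thz_dataset <- function(grid, absorbance, meta) {
  validate_grid(grid)
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(grid))
    stop("absorbance must have one column per grid frequency")
  if (any(!is.finite(absorbance)))
    stop("absorbance values must be finite")
  need <- c("sample_id", "replicate", analyte_names)
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(absorbance))
    stop("meta and absorbance must have the same number of rows")
  Y <- as.matrix(meta[, analyte_names])
  bad <- which(abs(rowSums(Y) - 1) > 1e-9 | Y < 0 | Y > 1)
  if (length(bad))
    stop("composition not on the simplex in row(s): ",
         paste(utils::head(unique((bad - 1) %% nrow(Y) + 1), 5), collapse = ", "))
  key <- paste(meta$sample_id, meta$replicate)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, replicate) pair(s): ",
         paste(utils::head(key[duplicated(key)], 5), collapse = "; "))
  reps <- table(meta$sample_id)
  if (length(unique(as.integer(reps))) > 1)
    stop("all samples must have the same replicate count")
  meta$mixture_order <- mixture_order(Y)
  if (is.null(meta$tag)) meta$tag <- NA_character_
  meta <- meta[, c("sample_id", "replicate", analyte_names, "mixture_order", "tag")]
  rownames(meta) <- NULL
  dimnames(absorbance) <- NULL
  structure(list(grid = grid, absorbance = absorbance, meta = meta),
            class = "thz_dataset")
}

#' @export
print.thz_dataset <- function(x, ...) {
  cat(sprintf("<thz_dataset> %d spectra of %d samples, %d features\n",
              nrow(x$absorbance), length(unique(x$meta$sample_id)),
              ncol(x$absorbance)))
  invisible(x)
}

#' Composition matrix of a dataset
#' @param dataset A `thz_dataset`.
#' @return `n x 3` numeric matrix of mass ratios, one row per spectrum.
#' @export
composition_matrix <- function(dataset) {
  Y <- as.matrix(dataset$meta[, analyte_names])
  rownames(Y) <- NULL
  Y
}

#' Subset a dataset by record index
#' @param dataset A `thz_dataset`.
#' @param idx Integer or logical row index.
#' @return A `thz_dataset` with the selected records.
#' @export
subset_records <- function(dataset, idx) {
  thz_dataset(dataset$grid, dataset$absorbance[idx, , drop = FALSE],
              dataset$meta[idx, , drop = FALSE])
}

# centered moving average with edge truncation (window shrinks near the ends)
moving_average <- function(x, window) {
  stopifnot(window >= 1, window <= length(x))
  if (window == 1) return(x)
  n <- length(x)
  half_lo <- (window - 1) %/% 2
  half_hi <- window - 1 - half_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# discrete-time Fourier transform of a real trace evaluated at arbitrary
# frequencies (THz); dt in picoseconds, so f*dt is dimensionless
dtft <- function(x, dt, freqs) {
  t_idx <- seq_along(x) - 1
  E <- exp(-2i * pi * outer(freqs, t_idx * dt))
  as.vector(E %*% x)
}

#' Convert a pair of time-domain traces to an absorbance spectrum
#'
#' Applies a centered moving average to each trace, Fourier-transforms both,
#' and forms the reference-compensated base-10 absorbance
#' \eqn{A(\omega) = \log_{10}|F_{ref}(\omega)| - \log_{10}|F_{sample}(\omega)|}
#' at each grid frequency. The transform is evaluated directly at the grid
#' frequencies (a discrete-time Fourier transform), so the grid need not be
#' commensurate with the trace length.
#'
#' @param sample,reference Numeric traces of equal length (field amplitude vs
#'   optical delay).
#' @param grid A [thz_grid()].
#' @param sampling_step Delay step of the traces in picoseconds.
#' @param smoothing_window Centered moving-average window (samples) applied to
#'   each trace before the transform; edge windows are truncated.
#' @return A numeric absorbance vector, one value per grid frequency.
#' @export
timetrace_to_absorbance <- function(sample, reference, grid,
                                    sampling_step,
                                    smoothing_window = 2000) {
  validate_grid(grid)
  if (length(sample) != length(reference))
    stop("sample and reference traces must have equal length")
  if (any(!is.finite(sample)) || any(!is.finite(reference)))
    stop("traces must be finite")
  if (smoothing_window < 1 || smoothing_window > length(sample))
    stop("smoothing_window must be in [1, trace length]")
  s <- moving_average(sample, smoothing_window)
  r <- moving_average(reference, smoothing_window)
  fr <- Mod(dtft(r, sampling_step, grid$frequencies))
  fs <- Mod(dtft(s, sampling_step, grid$frequencies))
  zero <- which(fr == 0)
  if (length(zero))
    stop(sprintf("reference magnitude is zero at %.4g THz",
                 grid$frequencies[zero[1]]))
  log10(fr) - log10(fs)
}

#' Write / read a spectra dataset as delimited text
#'
#' Layout: a header row naming the id columns followed by the grid
#' frequencies (THz, full precision), then one row per record:
#' `sample_id, replicate, caffeine, quinic_acid, nicotinic_acid, tag,`
#' followed by the absorbances. Floats are serialized at 17 significant
#' digits so a write/read round trip is bit-exact.
#'
#' @param dataset A `thz_dataset`.
#' @param path File path.
#' @return `read_thz_dataset` returns a `thz_dataset`; `write_thz_dataset`
#'   returns `path` invisibly.
#' @export
write_thz_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "thz_dataset"))
  fmt <- function(x) sprintf("%.17g", x)
  header <- c("sample_id", "replicate", analyte_names, "tag",
              fmt(dataset$grid$frequencies))
  m <- dataset$meta
  rows <- cbind(m$sample_id, m$replicate,
                fmt(m$caffeine), fmt(m$quinic_acid), fmt(m$nicotinic_acid),
                ifelse(is.na(m$tag), "", m$tag),
                matrix(fmt(dataset$absorbance), nrow = nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(rows, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_thz_dataset
#' @export
read_thz_dataset <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("dataset file must have a header and >= 1 record")
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  n_id <- 6L
  freqs <- as.numeric(header[-seq_len(n_id)])
  if (any(!is.finite(freqs))) stop("header frequencies are not numeric")
  res <- if (length(freqs) > 1) freqs[2] - freqs[1] else 0.005
  grid <- thz_grid(fmin = freqs[1] - res, fmax = freqs[length(freqs)],
                   resolution = res)
  ncol_expect <- n_id + length(freqs)
  body <- cells[-1]
  bad <- which(lengths(body) != ncol_expect)
  if (length(bad))
    stop("row length mismatch in data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  M <- do.call(rbind, body)
  meta <- data.frame(sample_id = M[, 1],
                     replicate = as.integer(M[, 2]),
                     caffeine = as.numeric(M[, 3]),
                     quinic_acid = as.numeric(M[, 4]),
                     nicotinic_acid = as.numeric(M[, 5]),
                     tag = ifelse(M[, 6] == "", NA_character_, M[, 6]),
                     stringsAsFactors = FALSE)
  ysum <- meta$caffeine + meta$quinic_acid + meta$nicotinic_acid
  bad <- which(abs(ysum - 1) > 1e-9)
  if (length(bad))
    stop("mass ratios do not sum to 1 in data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  A <- matrix(as.numeric(M[, -seq_len(n_id)]), nrow = nrow(M))
  thz_dataset(grid, A, meta)
}
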