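#' Construct a uniform terahertz frequency grid
#'
#' Builds the frequency axis on which all spectra in a dataset live. The
#' interval is half-open on the left, `(fmin, fmax]`, so that the default
#' 0.3--3.0 THz band sampled at 5 GHz yields exactly 540 points
#' (0.305, 0.310, ..., 3.000). This convention makes the instrument's stated
#' band and feature count hold simultaneously and is configurable.
#'
#' @param fmin Lower band edge in THz (excluded from the grid).
#' @param fmax Upper band edge in THz (included).
#' @param resolution Grid spacing in THz (5 GHz = 0.005 THz by default).
#' @return An object of class `thz_grid`: a list with elements `frequencies`
#'   (strictly increasing numeric vector, THz) and `resolution` (THz).
#' @examples
#' g <- thz_grid()
#' length(g$frequencies)  # 540
#' @export
thz_grid <- function(fmin = 0.3, fmax = 3.0, resolution = 0.005) {
  stopifnot(is.numeric(fmin), is.numeric(fmax), is.numeric(resolution),
            length(fmin) == 1, length(fmax) == 1, length(resolution) == 1,
            resolution > 0, fmax > fmin)
  n <- round((fmax - fmin) / resolution)
  if (abs(n * resolution - (fmax - fmin)) > 1e-9)
    stop("band width (fmin, fmax] is not an integer multiple of the resolution")
  freqs <- fmin + resolution * seq_len(n)
  structure(list(frequencies = freqs, resolution = resolution),
            class = "thz_grid")
}

#' @export
print.thz_grid <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("<thz_grid> %d points, (%.3f, %.3f] THz at %.4g THz spacing\n",
              length(f), f[1] - x$resolution, f[length(f)], x$resolution))
  invisible(x)
}

#' @export
length.thz_grid <- function(x) length(x$frequencies)

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "thz_grid"))
  f <- grid$frequencies
  if (length(f) < 1 || any(!is.finite(f)))
    stop("grid frequencies must be finite")
  d <- diff(f)
  if (length(d) && (any(d <= 0) || max(abs(d - grid$resolution)) > 1e-9))
    stop("grid must be strictly increasing with uniform spacing equal to the resolution")
  invisible(grid)
}

grids_identical <- function(a, b) {
  length(a$frequencies) == length(b$frequencies) &&
    max(abs(a$frequencies - b$frequencies)) <= 1e-12
}
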