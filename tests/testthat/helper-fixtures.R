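# shared fixtures: tiny grids, clean configs, and independent oracles

tiny_grid <- function(n = 54) thz_grid(0.3, 0.3 + 0.05 * n, 0.05)

# configuration with every stochastic nuisance switched off
clean_config <- function(..., seed = 7) {
  args <- utils::modifyList(
    list(noise_sd = 0, baseline_xi_range = c(0, 0), thickness_jitter = 0,
         nonlinearity_strength = 0, water_amplitude = 0, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# small random dataset-like matrix with reproducible contents
rand_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# independent Mie oracle: closed-form Riccati-Bessel functions from R's
# fractional-order Bessel routines, truncated at high fixed order with a
# finite-value guard (terms beyond are negligible)
qext_bessel_oracle <- function(m, x, N = 200) {
  # high orders underflow/overflow besselJ/besselY with a range warning;
  # the finite-value guard below discards those negligible terms
  psi <- function(n, z) suppressWarnings(sqrt(pi * z / 2) * besselJ(z, n + 0.5))
  chi <- function(n, z) suppressWarnings(-sqrt(pi * z / 2) * besselY(z, n + 0.5))
  mx <- m * x
  tot <- 0
  for (n in 1:N) {
    psin <- psi(n, x); psinm1 <- psi(n - 1, x)
    chin <- chi(n, x); chinm1 <- chi(n - 1, x)
    xin <- complex(real = psin, imaginary = -chin)
    xinm1 <- complex(real = psinm1, imaginary = -chinm1)
    psimn <- psi(n, mx); psimnm1 <- psi(n - 1, mx)
    dpsi <- psinm1 - n / x * psin
    dxin <- xinm1 - n / x * xin
    dpsim <- psimnm1 - n / mx * psimn
    if (any(!is.finite(c(psin, chin, psimn, dpsi, dpsim)))) break
    a_n <- (m * psimn * dpsi - psin * dpsim) /
      (m * psimn * dxin - xin * dpsim)
    b_n <- (psimn * dpsi - m * psin * dpsim) /
      (psimn * dxin - m * xin * dpsim)
    term <- (2 * n + 1) * Re(a_n + b_n)
    if (!is.finite(term)) break
    tot <- tot + term
  }
  2 / x^2 * tot
}

# brute-force discrete Fourier transform magnitude (naive loop oracle)
dtft_oracle <- function(x, dt, freqs) {
  sapply(freqs, function(f) {
    acc <- 0 + 0i
    for (t in seq_along(x))
      acc <- acc + x[t] * exp(-2i * pi * f * (t - 1) * dt)
    Mod(acc)
  })
}
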