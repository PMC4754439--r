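#' Fractional Gaussian noise by circulant embedding
#'
#' Generates stationary fractional Gaussian noise (fGn) with Hurst exponent
#' `hurst` using the Davies--Harte circulant embedding method, which is exact
#' in distribution: the sample has precisely the fGn autocovariance
#' \deqn{\gamma(k) = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right).}
#' An exact method (rather than approximate spectral filtering) is required
#' because these series serve as scaling-exponent oracles: DFA on fGn must
#' recover h(2) = H, and the lag-1 autocorrelation must equal
#' \eqn{2^{2H-1} - 1}.
#'
#' @param hurst Hurst exponent, in (0, 1). H = 0.5 gives white noise; H > 0.5
#'   long-range-persistent noise; H < 0.5 anti-persistent noise.
#' @param n number of samples, at least 16.
#' @param seed integer seed; the same (hurst, n, seed) always yields the
#'   identical series.
#' @return An [hrv_series] of length `n` with zero-mean unit-variance
#'   marginals.
#' @seealso [generate_fbm()] for the cumulative-sum (fractional Brownian
#'   motion) counterpart.
#' @export
generate_fgn <- function(hurst, n, seed) {
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1) {
    stop("`hurst` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 16L) stop("`n` must be at least 16", call. = FALSE)

  k <- 0:n
  gamma_k <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                      abs(k - 1)^(2 * hurst))
  # First row of the 2n-circulant embedding the (n+1)x(n+1) Toeplitz block.
  circ <- c(gamma_k, rev(gamma_k[2:n]))
  m <- length(circ)                      # = 2n
  lambda <- Re(stats::fft(circ))
  if (min(lambda) < -1e-8 * max(lambda)) {
    stop(
      "circulant embedding is not positive semi-definite at this n; ",
      "increase n",
      call. = FALSE
    )
  }
  lambda <- pmax(lambda, 0)

  with_seed(seed, {
    half <- m / 2                         # m is even by construction
    u <- stats::rnorm(half - 1)
    v <- stats::rnorm(half - 1)
    z0 <- stats::rnorm(1)
    zh <- stats::rnorm(1)
    a <- complex(length.out = m)
    a[1L] <- sqrt(lambda[1L] / m) * z0
    a[half + 1L] <- sqrt(lambda[half + 1L] / m) * zh
    idx <- 2:half
    a[idx] <- sqrt(lambda[idx] / (2 * m)) * complex(real = u, imaginary = v)
    a[m + 2L - idx] <- Conj(a[idx])
    x <- Re(stats::fft(a))[seq_len(n)]
    hrv_series(x, label = sprintf("fgn H=%.3g seed=%d", hurst, as.integer(seed)))
  })
}

#' Fractional Brownian motion
#'
#' Cumulative sum of [generate_fgn()]; the first value is the first fGn
#' increment, so `diff(c(0, fbm))` recovers the fGn series exactly.
#'
#' @inheritParams generate_fgn
#' @return An [hrv_series] of length `n`.
#' @export
generate_fbm <- function(hurst, n, seed) {
  incr <- generate_fgn(hurst, n, seed)
  hrv_series(
    cumsum(incr$values),
    label = sprintf("fbm H=%.3g seed=%d", hurst, as.integer(seed))
  )
}

#' Deterministic binomial multifractal cascade
#'
#' The standard multiplicative binomial measure on \eqn{2^{n_{levels}}}
#' points: \eqn{x_k = a^{b(k-1)} (1-a)^{n_{levels} - b(k-1)}} where
#' \eqn{b(\cdot)} counts ones in the binary expansion. Its generalized Hurst
#' exponents have the closed form
#' \deqn{h(q) = \frac{1}{q} - \frac{\ln(a^q + (1-a)^q)}{q \ln 2},}
#' making it the analytic oracle for the MF-DFA chain: h(q) is strictly
#' decreasing in q, so the series is genuinely multifractal.
#'
#' @param a multiplier, in (0.5, 1); larger `a` gives stronger
#'   multifractality.
#' @param n_levels number of cascade levels, 8 to 20; the series has
#'   `2^n_levels` points.
#' @return An [hrv_series] of length `2^n_levels`; deterministic (no seed).
#' @seealso [cascade_hq()] for the closed-form exponents.
#' @export
generate_binomial_cascade <- function(a, n_levels) {
  if (!is.numeric(a) || a <= 0.5 || a >= 1) {
    stop("`a` must lie strictly between 0.5 and 1", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  if (n_levels < 8L || n_levels > 20L) {
    stop("`n_levels` must be between 8 and 20", call. = FALSE)
  }
  n <- 2L^n_levels
  k <- 0:(n - 1L)
  ones <- integer(n)
  kk <- k
  while (any(kk > 0L)) {
    ones <- ones + (kk %% 2L)
    kk <- kk %/% 2L
  }
  x <- a^ones * (1 - a)^(n_levels - ones)
  hrv_series(x, label = sprintf("binomial cascade a=%.3g L=%d", a, n_levels))
}

#' Closed-form generalized Hurst exponents of the binomial cascade
#'
#' Returns \eqn{h(q) = 1/q - \ln(a^q + (1-a)^q)/(q \ln 2)} for each `q`.
#' At q = 0 the removable singularity is filled with its limit
#' \eqn{h(0) = -(\ln a + \ln(1-a)) / (2 \ln 2)}.
#'
#' @param a cascade multiplier in (0.5, 1).
#' @param q numeric vector of moment orders.
#' @return numeric vector, same length as `q`.
#' @export
cascade_hq <- function(a, q) {
  stopifnot(a > 0.5, a < 1)
  h <- numeric(length(q))
  zero <- abs(q) < 1e-8
  h[zero] <- -(log(a) + log(1 - a)) / (2 * log(2))
  qnz <- q[!zero]
  h[!zero] <- 1 / qnz - log(a^qnz + (1 - a)^qnz) / (qnz * log(2))
  h
}

#' BPM-like synthetic heart-rate series
#'
#' Structural stand-in for an instantaneous heart-rate recording, not a
#' physiological model: a constant baseline plus a slow sinusoidal
#' oscillation plus correlated (fGn) noise. Defaults give series that look
#' like resting human BPM traces (roughly 55--105 beats/minute with slow
#' respiratory-scale swings).
#'
#' @param baseline mean heart rate, beats/minute (> 0).
#' @param osc_amplitude amplitude of the slow oscillation, beats/minute.
#' @param osc_period oscillation period, in samples.
#' @param hurst Hurst exponent of the additive fGn noise.
#' @param noise_scale standard deviation of the noise, beats/minute.
#' @param n number of samples, at least 400.
#' @param seed integer seed.
#' @return An [hrv_series] with strictly positive values.
#' @export
generate_bpm_like <- function(baseline = 70, osc_amplitude = 5,
                              osc_period = 60, hurst = 0.8,
                              noise_scale = 3, n = 4096, seed = 1) {
  if (baseline <= 0) stop("`baseline` must be positive", call. = FALSE)
  n <- as.integer(n)
  if (n < 400L) stop("`n` must be at least 400", call. = FALSE)
  osc <- if (osc_amplitude == 0) {
    numeric(n)
  } else {
    osc_amplitude * sin(2 * pi * seq_len(n) / osc_period)
  }
  noise <- if (noise_scale == 0) {
    numeric(n)
  } else {
    # centred in-sample so `baseline` is the realised mean (up to the
    # oscillation's partial final period)
    z <- generate_fgn(hurst, n, seed)$values
    noise_scale * (z - mean(z))
  }
  x <- baseline + osc + noise
  if (any(x <= 0)) {
    stop(
      "parameters produced non-positive BPM values; reduce osc_amplitude ",
      "or noise_scale relative to baseline",
      call. = FALSE
    )
  }
  hrv_series(x, label = sprintf("bpm-like seed=%d", as.integer(seed)))
}

#' Shuffled surrogate of a series
#'
#' Uniform random permutation of the values (Fisher--Yates via
#' `sample.int`), preserving the value multiset exactly -- hence mean,
#' variance and every marginal moment -- while destroying all temporal
#' correlations. Used as the baseline against which correlation-driven
#' multifractality is judged: the spectrum width of the shuffle of a
#' long-range-correlated series is systematically smaller than that of the
#' original.
#'
#' @param series an [hrv_series] or numeric vector.
#' @param seed integer seed; same seed, same permutation.
#' @return An [hrv_series] with the permuted values (time stamps dropped:
#'   the surrogate has no meaningful time axis).
#' @export
shuffle_series <- function(series, seed) {
  x <- series_values(series)
  label <- if (inherits(series, "hrv_series")) series$label else ""
  perm <- with_seed(seed, sample.int(length(x)))
  hrv_series(
    x[perm],
    label = sprintf("%s [shuffled seed=%d]", label, as.integer(seed))
  )
}
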