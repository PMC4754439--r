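#' MF-DFA configuration
#'
#' Parameters of the multifractal detrended fluctuation analysis. Defaults
#' follow the standard choices for heart-rate series: 100 equidistant moment
#' orders q between -5 and +5, window sizes s log-spaced between 16 and 256
#' samples, and linear (order-1) detrending within each window.
#'
#' @param q_grid numeric vector of moment orders. Values with |q| below
#'   machine tolerance are routed through the q -> 0 logarithmic-average
#'   limit of the fluctuation function.
#' @param scale_grid integer vector of window sizes s. The default lays
#'   `n_scales` points equispaced in log2 between `s_min` and `s_max`,
#'   rounds to integers and deduplicates.
#' @param order polynomial detrending order m (1 = linear).
#' @param s_min,s_max,n_scales used only to build the default `scale_grid`.
#' @param bidirectional if `TRUE`, windows are taken from both ends of the
#'   profile (2 Ns windows, the Kantelhardt variant); the default `FALSE`
#'   uses forward-only windows, discarding the tail remainder.
#' @return A list of class `mfdfa_config`.
#' @export
mfdfa_config <- function(q_grid = seq(-5, 5, length.out = 100),
                         scale_grid = NULL,
                         order = 1L,
                         s_min = 16L, s_max = 256L, n_scales = 16L,
                         bidirectional = FALSE) {
  order <- as.integer(order)
  if (order < 0L) stop("`order` must be >= 0", call. = FALSE)
  if (is.null(scale_grid)) {
    scale_grid <- unique(as.integer(round(
      2^seq(log2(s_min), log2(s_max), length.out = n_scales)
    )))
  } else {
    scale_grid <- sort(unique(as.integer(scale_grid)))
  }
  if (any(scale_grid < order + 2L)) {
    stop("all scales must be at least order + 2", call. = FALSE)
  }
  if (!all(is.finite(q_grid))) stop("`q_grid` must be finite", call. = FALSE)
  structure(
    list(q_grid = as.numeric(q_grid), scale_grid = scale_grid,
         order = order, bidirectional = isTRUE(bidirectional)),
    class = "mfdfa_config"
  )
}

#' Profile (integrated series) of a signal
#'
#' Step 1 of MF-DFA: the cumulative sum of the mean-subtracted signal,
#' \eqn{Y(i) = \sum_{k=1}^{i} (x(k) - \bar x)}. By construction Y(N) = 0 up
#' to rounding. A constant input yields an all-zero profile, which is legal
#' here but makes every detrended window degenerate downstream.
#'
#' @param series an [hrv_series] or numeric vector, length >= 2.
#' @return numeric vector of the same length.
#' @export
compute_profile <- function(series) {
  x <- if (inherits(series, "hrv_series")) series$values else as.numeric(series)
  if (length(x) < 2L) stop("series too short", call. = FALSE)
  cumsum(x - mean(x))
}

#' Mean squared detrending residual of one window
#'
#' Step 2 of MF-DFA for a single window: the profile segment
#' `Y[(v-1)s + 1 .. vs]` is fitted with an order-`m` least-squares polynomial
#' and the mean of the squared residuals is returned,
#' \eqn{F^2(s, v) = \frac1s \sum_{i=1}^{s} (Y[(v-1)s+i] - y_v(i))^2.}
#'
#' Exposed mainly for inspection and testing; [fluctuation_function()] does
#' the same computation for all windows at once.
#'
#' @param profile numeric profile from [compute_profile()].
#' @param s window length.
#' @param v window index, 1-based, at most `floor(length(profile)/s)`.
#' @param m polynomial order.
#' @return a single non-negative number.
#' @export
local_rms <- function(profile, s, v, m = 1L) {
  s <- as.integer(s); v <- as.integer(v); m <- as.integer(m)
  n_s <- length(profile) %/% s
  if (v < 1L || v > n_s) stop("window index out of range", call. = FALSE)
  if (s < m + 2L) stop("window shorter than order + 2", call. = FALSE)
  y <- profile[((v - 1L) * s + 1L):(v * s)]
  design <- outer(seq_len(s), 0:m, `^`)
  mean(qr.resid(qr(design), y)^2)
}

# Detrend every length-s window of the profile at once: reshape into an
# s x Ns matrix and project out the order-m polynomial column space via a
# single QR factorisation shared by all windows.
window_f2 <- function(profile, s, m, bidirectional = FALSE) {
  n <- length(profile)
  n_s <- n %/% s
  if (n_s < 1L) return(numeric(0))
  seg <- matrix(profile[seq_len(n_s * s)], nrow = s)
  if (bidirectional && n_s * s < n) {
    seg2 <- matrix(profile[(n - n_s * s + 1L):n], nrow = s)
    seg <- cbind(seg, seg2)
  }
  x <- seq_len(s)
  design <- outer(x, 0:m, `^`)
  qrd <- qr(design)
  resid <- qr.resid(qrd, seg)
  colMeans(resid^2)
}

#' q-order fluctuation function
#'
#' Steps 2--3 of MF-DFA: for every scale s in the config the profile is cut
#' into `Ns = floor(N/s)` non-overlapping windows, each window is detrended
#' by an order-m polynomial, and the q-order mean of the squared residuals
#' is formed,
#' \deqn{F_q(s) = \left\{ \frac{1}{N_s}\sum_{v=1}^{N_s}
#'   [F^2(s,v)]^{q/2} \right\}^{1/q},}
#' with the q -> 0 logarithmic limit
#' \eqn{F_0(s) = \exp\{\frac{1}{2N_s}\sum_v \ln F^2(s,v)\}.}
#'
#' By the generalized-mean inequality \eqn{F_{q_1}(s) \le F_{q_2}(s)}
#' whenever \eqn{q_1 \le q_2}, at every s.
#'
#' @param series an [hrv_series] or numeric vector with
#'   `N >= 4 * max(scale_grid)`.
#' @param config an [mfdfa_config()].
#' @return numeric matrix, rows = q values, cols = scales, with the grids in
#'   `dimnames`.
#' @export
fluctuation_function <- function(series, config = mfdfa_config()) {
  x <- series_values(series)
  n <- length(x)
  if (n < 4L * max(config$scale_grid)) {
    stop("series must be at least 4 times the largest scale", call. = FALSE)
  }
  profile <- compute_profile(x)
  q <- config$q_grid
  fq <- matrix(NA_real_, nrow = length(q), ncol = length(config$scale_grid),
               dimnames = list(q = format(q, digits = 6),
                               s = config$scale_grid))
  for (j in seq_along(config$scale_grid)) {
    s <- config$scale_grid[j]
    f2 <- window_f2(profile, s, config$order, config$bidirectional)
    if (any(f2 == 0) && any(q < 0)) {
      stop(
        "degenerate window (zero detrending residual) at scale ", s,
        " makes negative-q moments infinite; reduce the detrending order ",
        "or exclude this scale",
        call. = FALSE
      )
    }
    for (i in seq_along(q)) {
      fq[i, j] <- if (abs(q[i]) < 1e-6) {
        exp(mean(log(f2)) / 2)
      } else {
        mean(f2^(q[i] / 2))^(1 / q[i])
      }
    }
  }
  fq
}

#' Generalized Hurst exponents from the fluctuation surface
#'
#' Step 4 of MF-DFA: for each q, the ordinary least-squares slope of
#' log2 Fq(s) on log2 s is the generalized Hurst exponent h(q). Non-finite
#' surface entries are dropped per q; fewer than 4 usable scales is an
#' error.
#'
#' @param fq_surface matrix from [fluctuation_function()] (rows q, cols s).
#' @param scale_grid integer vector of scales matching the columns.
#' @return data.frame with columns `q`, `h`, `se` (slope standard error) and
#'   `r_squared`.
#' @export
generalized_hurst <- function(fq_surface, scale_grid) {
  stopifnot(ncol(fq_surface) == length(scale_grid))
  q <- as.numeric(rownames(fq_surface))
  if (anyNA(q)) q <- seq_len(nrow(fq_surface))
  out <- data.frame(q = q, h = NA_real_, se = NA_real_, r_squared = NA_real_)
  lx_all <- log2(scale_grid)
  for (i in seq_len(nrow(fq_surface))) {
    y <- fq_surface[i, ]
    ok <- is.finite(y) & y > 0
    if (sum(ok) < 4L) {
      stop("fewer than 4 finite scales for q = ", q[i], call. = FALSE)
    }
    fit <- ols_fit(lx_all[ok], log2(y[ok]))
    out$h[i] <- fit$slope
    out$se[i] <- fit$se
    out$r_squared[i] <- fit$r_squared
  }
  out
}

#' Mass exponent tau(q)
#'
#' \eqn{\tau(q) = q h(q) - 1}. Linear in q exactly when h(q) is constant
#' (monofractal); curvature of tau(q) is the signature of multifractality.
#'
#' @param h_q numeric vector of generalized Hurst exponents.
#' @param q_grid matching numeric vector of moment orders.
#' @return numeric vector of the same length.
#' @export
tau_from_h <- function(h_q, q_grid) {
  stopifnot(length(h_q) == length(q_grid), all(is.finite(h_q)))
  q_grid * h_q - 1
}

#' Singularity spectrum via the Legendre transform
#'
#' \eqn{\alpha = h(q) + q h'(q)} and \eqn{f(\alpha) = q[\alpha - h(q)] + 1},
#' with h'(q) from central finite differences on the q grid (one-sided at
#' the two endpoints). For a monofractal (constant h) the spectrum collapses
#' to the single point (H, 1); for a multifractal it is a concave arc with
#' apex near 1 attained around q = 0. A non-monotone alpha (noisy h(q)) is
#' retained and flagged, and the width is still max - min.
#'
#' @param h_q numeric vector of generalized Hurst exponents, length >= 3.
#' @param q_grid matching moment orders.
#' @return data.frame with columns `q`, `alpha`, `f_alpha`, plus attribute
#'   `monotone_alpha` (logical).
#' @export
singularity_spectrum <- function(h_q, q_grid) {
  stopifnot(length(h_q) == length(q_grid), length(h_q) >= 3L)
  n <- length(q_grid)
  dh <- numeric(n)
  dh[1L] <- (h_q[2L] - h_q[1L]) / (q_grid[2L] - q_grid[1L])
  dh[n] <- (h_q[n] - h_q[n - 1L]) / (q_grid[n] - q_grid[n - 1L])
  if (n > 2L) {
    idx <- 2:(n - 1L)
    dh[idx] <- (h_q[idx + 1L] - h_q[idx - 1L]) /
      (q_grid[idx + 1L] - q_grid[idx - 1L])
  }
  alpha <- h_q + q_grid * dh
  f_alpha <- q_grid * (alpha - h_q) + 1
  out <- data.frame(q = q_grid, alpha = alpha, f_alpha = f_alpha)
  attr(out, "monotone_alpha") <- !is.unsorted(rev(alpha)) || !is.unsorted(alpha)
  out
}

#' Multifractal spectrum width
#'
#' \eqn{\Delta\alpha = \max(\alpha) - \min(\alpha)} over the computed
#' spectrum -- the headline multifractality measure. Zero for a perfect
#' monofractal; larger widths mean a broader range of local scaling
#' exponents.
#'
#' @param alpha numeric vector of singularity strengths (or the data.frame
#'   from [singularity_spectrum()]).
#' @return a single non-negative number.
#' @export
spectrum_width <- function(alpha) {
  if (is.data.frame(alpha)) alpha <- alpha$alpha
  if (length(alpha) == 0L) stop("`alpha` is empty", call. = FALSE)
  max(alpha) - min(alpha)
}

#' Run the full MF-DFA chain
#'
#' Profile, windowed detrending, q-order fluctuation functions, generalized
#' Hurst exponents, mass exponents, singularity spectrum and its width, in
#' one call. All intermediates are kept on the result for inspection.
#'
#' The method needs long series: below roughly 1024 samples the scaling
#' regression is dominated by finite-size effects and a warning is issued
#' (the analysis still runs if `N >= 4 * max(scale)` holds).
#'
#' @param series an [hrv_series] or numeric vector.
#' @param config an [mfdfa_config()].
#' @return An object of class `mfdfa_result`: list with `q_grid`,
#'   `scale_grid`, `fq_surface`, `hurst_q` (data.frame q/h/se/r_squared),
#'   `tau_q`, `spectrum` (q/alpha/f_alpha), `width`, `config`, `label`.
#' @examples
#' casc <- generate_binomial_cascade(0.75, 10)
#' res <- run_mfdfa(casc, mfdfa_config(q_grid = seq(-5, 5, by = 0.5),
#'                                     s_max = 128))
#' res$width
#' @export
run_mfdfa <- function(series, config = mfdfa_config()) {
  x <- series_values(series)
  if (length(x) < 1024L) {
    warning("MF-DFA is unreliable below about 1024 samples; ",
            "interpret the width with caution", call. = FALSE)
  }
  fq <- fluctuation_function(x, config)
  hq <- generalized_hurst(fq, config$scale_grid)
  tau <- tau_from_h(hq$h, config$q_grid)
  spec <- singularity_spectrum(hq$h, config$q_grid)
  structure(
    list(
      q_grid = config$q_grid,
      scale_grid = config$scale_grid,
      fq_surface = fq,
      hurst_q = hq,
      tau_q = tau,
      spectrum = spec,
      width = spectrum_width(spec$alpha),
      config = config,
      label = if (inherits(series, "hrv_series")) series$label else ""
    ),
    class = "mfdfa_result"
  )
}

#' @export
print.mfdfa_result <- function(x, ...) {
  h2 <- x$hurst_q$h[which.min(abs(x$hurst_q$q - 2))]
  cat(sprintf(
    "<mfdfa_result>%s\n  q in [%.3g, %.3g] (%d values), s in [%d, %d] (%d scales), m = %d\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    min(x$q_grid), max(x$q_grid), length(x$q_grid),
    min(x$scale_grid), max(x$scale_grid), length(x$scale_grid),
    x$config$order
  ))
  cat(sprintf("  h(q~2) = %.4f, spectrum width = %.4f\n", h2, x$width))
  invisible(x)
}
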