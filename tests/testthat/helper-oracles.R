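# Independent oracles, deliberately coded by the dumbest correct route so
# they share nothing with the implementation they check.

# Exact fGn autocovariance at lag k.
fgn_gamma <- function(H, k) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Autocovariance estimator for a process with known zero mean (the
# mean-subtracted estimator is biased downward for long-range-dependent
# series, which would corrupt the oracle).
acov_zero_mean <- function(x, k) {
  n <- length(x)
  mean(x[seq_len(n - k)] * x[(k + 1):n])
}

# Closed-form generalized Hurst exponent of the binomial cascade, written
# out independently of cascade_hq().
cascade_h_closed <- function(a, q) {
  1 / q - log(a^q + (1 - a)^q) / (q * log(2))
}

# O(n^3) exhaustive visibility check. The defining strict inequality
# ("every intermediate sample lies strictly below the chord") is evaluated
# in its slope form, x[t] blocks (m, nn) iff
#   (x[t] - x[m]) / (t - m) >= (x[nn] - x[m]) / (nn - m),
# which is algebraically identical to the chord-anchored form and, unlike
# it, classifies exactly collinear points exactly (no mixed rounding of
# (nn - t)/(nn - m) products), so ties resolve identically in any faithful
# implementation.
vg_edges_bruteforce <- function(x) {
  n <- length(x)
  edges <- NULL
  for (m in seq_len(n - 1)) {
    for (nn in (m + 1):n) {
      chord_slope <- (x[nn] - x[m]) / (nn - m)
      visible <- TRUE
      if (nn > m + 1) {
        for (t in (m + 1):(nn - 1)) {
          if ((x[t] - x[m]) / (t - m) >= chord_slope) {
            visible <- FALSE
            break
          }
        }
      }
      if (visible) edges <- rbind(edges, c(m, nn))
    }
  }
  edges
}

# Least-squares polynomial residual mean square via explicit normal
# equations (solve(t(X) X) t(X) y), no QR.
lsq_rms_normal_eq <- function(y, m) {
  s <- length(y)
  X <- outer(seq_len(s), 0:m, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  mean((y - X %*% beta)^2)
}

edge_key <- function(edges) {
  paste(edges[, 1], edges[, 2], sep = "-")
}
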