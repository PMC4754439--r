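test_that("profile is the cumulative mean-subtracted sum", {
  expect_equal(compute_profile(c(1, 2, 3)), c(-1, -1, 0))
  expect_equal(compute_profile(c(5, 5, 5, 5)), c(0, 0, 0, 0))
  x <- generate_bpm_like(n = 1000, seed = 3)$values
  p <- compute_profile(x)
  expect_lt(abs(p[length(p)]), 1e-9 * length(x) * max(abs(x)))
})

test_that("local_rms matches hand values and a normal-equations oracle", {
  # linear profile segment, linear detrend: zero residual
  expect_equal(local_rms(2 * (1:8) + 3, 8, 1, m = 1), 0)
  # one bin [0,1,0,-1], m = 0: residual variance about the mean is 0.5
  expect_equal(local_rms(c(0, 1, 0, -1), 4, 1, m = 0), 0.5)

  # oracle equivalence on 100 random bins, m = 1
  prof <- compute_profile(generate_fgn(0.7, 4096, 9)$values)
  set.seed(42)
  for (i in 1:100) {
    s <- sample(8:64, 1)
    v <- sample(length(prof) %/% s, 1)
    seg <- prof[((v - 1) * s + 1):(v * s)]
    got <- local_rms(prof, s, v, m = 1)
    want <- lsq_rms_normal_eq(seg, 1)
    expect_equal(got, want, tolerance = 1e-10)
  }

  expect_error(local_rms(1:10, 5, 3, m = 1), "out of range")
  expect_error(local_rms(1:10, 2, 1, m = 1), "shorter")
})

test_that("fluctuation function obeys the generalized-mean structure", {
  cfg <- mfdfa_config(q_grid = c(-5, -2, 0, 2, 5), scale_grid = c(16, 24, 32, 48, 64))
  x <- generate_fgn(0.6, 2048, 5)
  fq <- fluctuation_function(x, cfg)
  expect_true(all(is.finite(fq)) && all(fq > 0))
  # monotone non-decreasing in q at every scale (generalized-mean inequality)
  for (j in seq_len(ncol(fq))) {
    expect_true(all(diff(fq[, j]) >= -1e-12), label = paste("q-ordering at s =", cfg$scale_grid[j]))
  }
  # q -> 0 column sits between its neighbours
  expect_true(all(fq[2, ] <= fq[3, ] & fq[3, ] <= fq[4, ]))

  # equal F2 in every window => F_q(s) = sqrt(F2) for all q, including q = 0:
  # a sine whose period divides every window length gives identical windows
  xs <- sin(2 * pi * seq_len(1024) / 16)
  cfg2 <- mfdfa_config(q_grid = c(-4, 0, 4), scale_grid = c(16, 32, 64), order = 0)
  fq2 <- fluctuation_function(xs, cfg2)
  expect_equal(fq2[1, ], fq2[2, ], tolerance = 1e-6)
  expect_equal(fq2[1, ], fq2[3, ], tolerance = 1e-6)

  # white noise: F_2(s) grows like s^0.5
  cfg3 <- mfdfa_config(q_grid = 2, scale_grid = c(16, 32, 64, 128, 256))
  fq3 <- fluctuation_function(generate_fgn(0.5, 2^13, 8), cfg3)
  slope <- generalized_hurst(fq3, cfg3$scale_grid)$h
  expect_lt(abs(slope - 0.5), 0.1)

  # degenerate (constant) windows with negative q are a loud error
  expect_error(
    fluctuation_function(rep(5, 256), mfdfa_config(q_grid = -2, scale_grid = 16)),
    "degenerate"
  )

  expect_error(fluctuation_function(1:100, mfdfa_config()), "4 times")
})

test_that("generalized Hurst regression recovers exact and stochastic slopes", {
  scales <- c(16, 32, 64, 128, 256)
  fq <- matrix(scales^0.7, nrow = 1)
  rownames(fq) <- "2"
  fit <- generalized_hurst(fq, scales)
  expect_equal(fit$h, 0.7, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # h(2) ~ 0.5 for white noise, averaged over seeds
  cfg <- mfdfa_config(q_grid = 2)
  h2 <- vapply(1:10, function(s) {
    generalized_hurst(fluctuation_function(generate_fgn(0.5, 2^13, s), cfg),
                      cfg$scale_grid)$h
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.1)
})

test_that("h(2) recovery holds across Hurst exponents for fGn", {
  cfg <- mfdfa_config(q_grid = 2)
  for (H in c(0.3, 0.5, 0.7)) {
    h2 <- vapply(1:10, function(s) {
      generalized_hurst(fluctuation_function(generate_fgn(H, 2^13, s), cfg),
                        cfg$scale_grid)$h
    }, numeric(1))
    expect_lt(abs(mean(h2) - H), 0.1, label = sprintf("h(2) bias at H=%.1f", H))
  }
})

test_that("tau(q) is q h(q) - 1 and linear exactly for monofractals", {
  expect_equal(tau_from_h(0.5, 2), 0)
  q <- seq(-5, 5, by = 0.5)
  tau <- tau_from_h(rep(0.62, length(q)), q)
  expect_equal(max(abs(diff(diff(tau)))), 0, tolerance = 1e-12)

  # cascade: tau(q) = -log2(a^q + (1-a)^q) within 0.1 at q = +/-2
  a <- 0.6
  cfg <- mfdfa_config(q_grid = c(-2, 2), n_scales = 5)
  hq <- generalized_hurst(
    fluctuation_function(generate_binomial_cascade(a, 13), cfg),
    cfg$scale_grid
  )
  tau_hat <- tau_from_h(hq$h, hq$q)
  tau_true <- -log2(a^hq$q + (1 - a)^hq$q)
  expect_lt(max(abs(tau_hat - tau_true)), 0.1)
})

test_that("singularity spectrum collapses for monofractals and arcs for cascades", {
  q <- seq(-5, 5, length.out = 21)
  spec <- singularity_spectrum(rep(0.8, 21), q)
  expect_equal(spec$alpha, rep(0.8, 21), tolerance = 1e-12)
  expect_equal(spec$f_alpha, rep(1, 21), tolerance = 1e-12)
  expect_equal(spectrum_width(spec), 0)

  # linear h(q) = c - b q: f(alpha(0)) = 1 by substitution
  b <- 0.04; cc <- 0.9
  spec2 <- singularity_spectrum(cc - b * q, q)
  expect_equal(spec2$f_alpha[q == 0], 1, tolerance = 1e-10)

  # cascade spectrum: concave arc with apex ~ 1
  res <- run_mfdfa(generate_binomial_cascade(0.6, 13),
                   mfdfa_config(n_scales = 5))
  expect_lt(abs(max(res$spectrum$f_alpha) - 1), 0.05)
})

test_that("spectrum width is max - min of alpha", {
  expect_equal(spectrum_width(c(0.3, 0.5, 0.9)), 0.6)
  expect_equal(spectrum_width(0.7), 0)
})

test_that("full MF-DFA run separates cascade from white noise and is deterministic", {
  w_casc <- run_mfdfa(generate_binomial_cascade(0.75, 13))$width
  w_noise <- run_mfdfa(generate_fgn(0.5, 2^13, 1))$width
  expect_gt(w_casc, 0.5)
  expect_lt(w_noise, 0.3)

  r1 <- run_mfdfa(generate_fgn(0.7, 2^12, 2))
  r2 <- run_mfdfa(generate_fgn(0.7, 2^12, 2))
  expect_identical(r1$fq_surface, r2$fq_surface)
  expect_identical(r1$width, r2$width)

  expect_warning(run_mfdfa(generate_fgn(0.5, 900, 1),
                           mfdfa_config(scale_grid = c(16, 32, 64, 128),
                                        n_scales = 4)),
                 "unreliable")
})

test_that("shuffling lowers the average spectrum width of correlated noise", {
  # Destroying the temporal correlations of persistent noise removes its
  # finite-size width excess: the paired mean difference is positive.
  cfg <- mfdfa_config()
  diffs <- vapply(1:10, function(s) {
    x <- generate_fgn(0.9, 2^13, s)
    w_orig <- run_mfdfa(x, cfg)$width
    w_shuf <- mean(vapply(1:5, function(r) {
      run_mfdfa(shuffle_series(x, s * 100 + r), cfg)$width
    }, numeric(1)))
    w_orig - w_shuf
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("white-noise width stays below cascade width across paired seeds", {
  cfg <- mfdfa_config(q_grid = seq(-5, 5, length.out = 25))
  w_casc <- run_mfdfa(generate_binomial_cascade(0.75, 12), cfg)$width
  for (s in 1:10) {
    w_noise <- run_mfdfa(generate_fgn(0.5, 2^12, s), cfg)$width
    expect_lt(w_noise, w_casc, label = sprintf("seed %d", s))
  }
})
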