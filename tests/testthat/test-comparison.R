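test_that("percent increase matches the published subject C1 arithmetic", {
  expect_equal(round(percent_increase(3.22, 5.49), 1), 70.5)
  expect_equal(percent_increase(0.24, 0.66), 175)
  expect_equal(percent_increase(4.2, 4.2), 0)
  expect_error(percent_increase(0, 1), "positive")
  expect_error(percent_increase(-2, 1), "positive")
})

test_that("percent increase inverts exactly", {
  set.seed(31)
  pre <- runif(50, 0.1, 10)
  med <- runif(50, 0.1, 10)
  p <- percent_increase(pre, med)
  expect_equal(pre * (1 + p / 100), med, tolerance = 1e-12)
})

test_that("pearson guards its preconditions and is affine-invariant", {
  ys <- c(1, 3, 2, 5, 4)
  expect_equal(pearson(2 * ys + 1, ys), 1)
  xs <- c(0.3, 1.2, 0.8, 2.2, 1.4)
  r <- pearson(xs, ys)
  expect_equal(pearson(10 * xs - 3, ys), r, tolerance = 1e-12)
  expect_equal(pearson(xs, 0.2 * ys + 7), r, tolerance = 1e-12)
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), ys), "zero variance")
})

test_that("analyze_subject assembles both methods with suppression contract", {
  pre <- generate_fgn(0.55, 2048, 1)
  med <- generate_fgn(0.9, 2048, 1)
  cfg <- mfdfa_config(q_grid = seq(-5, 5, length.out = 25))
  cmp <- analyze_subject(pre, med, subject_id = "S1", config = cfg,
                         shuffle_seed = 3)
  expect_s3_class(cmp, "subject_comparison")
  expect_false(anyNA(cmp[, c("width_med", "width_pre",
                             "shuffled_width_med", "shuffled_width_pre")]))
  expect_equal(cmp$pct_increase_lambda,
               percent_increase(cmp$lambda_pre, cmp$lambda_med))

  # identical states: both increases exactly zero
  same <- analyze_subject(pre, pre, config = cfg)
  expect_equal(same$pct_increase_lambda, 0)
  expect_equal(same$pct_increase_width, 0)

  # short record: MF-DFA suppressed by the length rule, PSVG still present
  short_pre <- generate_bpm_like(n = 700, seed = 5)
  short_med <- generate_bpm_like(n = 700, seed = 6)
  sup <- analyze_subject(short_pre, short_med)
  expect_true(is.na(sup$width_med) && is.na(sup$width_pre))
  expect_true(is.na(sup$pct_increase_width))
  expect_false(is.na(sup$lambda_med) || is.na(sup$lambda_pre))
})

test_that("a rougher, more multifractal meditation stand-in raises both markers", {
  # 'pre' is a smooth monofractal walk; 'med' is a multifractal random walk
  # (cascade-modulated, anti-persistent increments, integrated): rougher
  # (higher fractal dimension, so larger lambda_p) AND more multifractal
  # (wider spectrum). Both methods should rank med > pre concordantly in a
  # clear majority of seeds -- the double-checking logic.
  cfg <- mfdfa_config(q_grid = seq(-5, 5, length.out = 25))
  n <- 2^12
  vol <- generate_binomial_cascade(0.7, 12)$values  # deterministic volatility
  lam_up <- width_up <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    pre <- generate_fbm(0.65, n, s)
    med <- hrv_series(cumsum(sqrt(n * vol) *
                               generate_fgn(0.3, n, s + 500)$values))
    cmp <- analyze_subject(pre, med, config = cfg, suppress_mfdfa = FALSE)
    lam_up <- lam_up + (cmp$lambda_med > cmp$lambda_pre)
    width_up <- width_up + (cmp$width_med > cmp$width_pre)
  }
  expect_gte(lam_up, 8)
  expect_gte(width_up, 8)
})

test_that("build_table aggregates rows, groups and correlations", {
  pub <- published_meditation_values()
  tab <- build_table(pub)
  expect_s3_class(tab, "comparison_table")
  expect_equal(nrow(tab$rows), 12L)

  gs <- tab$group_summary
  chi <- gs[gs$group == "chi", ]
  expect_equal(chi$n_subjects, 8)
  expect_equal(round(chi$max_pct_lambda, 1), 70.5)
  expect_equal(round(chi$max_pct_width, 1), 175)
  # width extremes computed only over subjects with MF-DFA present
  kun <- gs[gs$group == "kundalini", ]
  expect_true(is.na(kun$min_pct_width))

  # single subject: min = max = that subject's increase
  one <- build_table(pub[1, ])
  expect_equal(one$group_summary$min_pct_lambda,
               one$group_summary$max_pct_lambda)

  # correlations only use rows where both methods are present (the 8 Chi)
  expect_equal(tab$correlations$r_med,
               pearson(pub$lambda_med[1:8], pub$width_med[1:8]))
})

test_that("pipeline output is bit-stable across repeated runs", {
  pre <- generate_bpm_like(n = 1100, seed = 21)
  med <- generate_bpm_like(n = 1100, seed = 22, osc_amplitude = 8)
  cfg <- mfdfa_config(q_grid = seq(-5, 5, length.out = 25),
                      scale_grid = c(16, 32, 64, 128, 256))
  a <- analyze_subject(pre, med, config = cfg, shuffle_seed = 9)
  b <- analyze_subject(pre, med, config = cfg, shuffle_seed = 9)
  expect_identical(a, b)
})
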