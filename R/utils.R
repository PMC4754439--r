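# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All seeded operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Ordinary least squares of y on x with slope standard error and R^2.
# Small enough that calling lm() per q value would be overkill.
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("zero variance in predictor", call. = FALSE)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - yb)^2)
  se <- if (n > 2L) sqrt(rss / (n - 2L) / sxx) else NA_real_
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(slope = slope, intercept = intercept, se = se, r_squared = r2)
}
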