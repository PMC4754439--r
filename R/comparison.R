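#' Percent increase from a baseline value
#'
#' \eqn{100 (med - pre) / pre}: sign-preserving, zero when the two values
#' are equal. The baseline must be positive.
#'
#' @param pre_value baseline (pre-meditation) value, > 0.
#' @param med_value comparison (meditation) value.
#' @return percent change, vectorised over both arguments.
#' @examples
#' percent_increase(3.22, 5.49)  # 70.5
#' @export
percent_increase <- function(pre_value, med_value) {
  if (any(pre_value <= 0, na.rm = TRUE)) {
    stop("baseline value must be positive", call. = FALSE)
  }
  100 * (med_value - pre_value) / pre_value
}

#' Pearson correlation with validity checks
#'
#' Sample Pearson correlation via [stats::cor()], guarded: equal lengths of
#' at least 3 and nonzero variance in both arguments are required. Used for
#' the cross-method check correlating PSVG exponents with multifractal
#' spectrum widths across subjects.
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3L) {
    stop("need equal-length vectors with at least 3 observations",
         call. = FALSE)
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(xs, ys, method = "pearson")
}

#' Compare one subject's pre-meditation and meditation series
#'
#' Runs the visibility-graph exponent on both states, and -- unless
#' suppressed -- MF-DFA on both states plus a shuffled surrogate of each as
#' the no-correlation baseline. MF-DFA is suppressed by default when either
#' series is shorter than `mfdfa_floor` samples, since the multifractal
#' width is unreliable on short records while the PSVG exponent is not;
#' suppressed width fields are `NA`.
#'
#' @param pre_series,med_series [hrv_series] (or numeric vectors) for the
#'   two states.
#' @param subject_id label for the subject.
#' @param config an [mfdfa_config()] for the width computations.
#' @param shuffle_seed integer seed for the surrogate permutations.
#' @param shuffle_reps number of independent shuffles averaged per state
#'   (default 1, one surrogate width per state).
#' @param suppress_mfdfa force-suppress (`TRUE`) or force-run (`FALSE`)
#'   MF-DFA; `NULL` (default) applies the `mfdfa_floor` length rule.
#' @param mfdfa_floor series length below which MF-DFA is suppressed.
#' @return An object of class `subject_comparison`: one-row data.frame with
#'   columns `subject`, `lambda_med`, `lambda_pre`, `width_med`,
#'   `width_pre`, `shuffled_width_med`, `shuffled_width_pre`,
#'   `pct_increase_lambda`, `pct_increase_width`.
#' @export
analyze_subject <- function(pre_series, med_series, subject_id = "S1",
                            config = mfdfa_config(), shuffle_seed = 1L,
                            shuffle_reps = 1L, suppress_mfdfa = NULL,
                            mfdfa_floor = 1024L) {
  n_pre <- length(series_values(pre_series))
  n_med <- length(series_values(med_series))
  if (is.null(suppress_mfdfa)) {
    suppress_mfdfa <- min(n_pre, n_med) < mfdfa_floor
  }

  lam_pre <- psvg_of_series(pre_series)$lambda_p
  lam_med <- psvg_of_series(med_series)$lambda_p

  if (suppress_mfdfa) {
    w_pre <- w_med <- sw_pre <- sw_med <- NA_real_
  } else {
    w_pre <- run_mfdfa(pre_series, config)$width
    w_med <- run_mfdfa(med_series, config)$width
    shuffled_width <- function(series, base_seed) {
      mean(vapply(seq_len(shuffle_reps), function(r) {
        run_mfdfa(shuffle_series(series, base_seed + r - 1L), config)$width
      }, numeric(1L)))
    }
    sw_pre <- shuffled_width(pre_series, shuffle_seed)
    sw_med <- shuffled_width(med_series, shuffle_seed + 10000L)
  }

  out <- data.frame(
    subject = subject_id,
    lambda_med = lam_med, lambda_pre = lam_pre,
    width_med = w_med, width_pre = w_pre,
    shuffled_width_med = sw_med, shuffled_width_pre = sw_pre,
    pct_increase_lambda = percent_increase(lam_pre, lam_med),
    pct_increase_width = if (suppress_mfdfa || w_pre <= 0) NA_real_ else
      percent_increase(w_pre, w_med),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_comparison", class(out))
  out
}

#' Aggregate subject comparisons into a summary table
#'
#' Stacks per-subject rows and computes the study-level summaries: per-group
#' minimum and maximum percent increases of each exponent, per-state group
#' means of the PSVG exponent, and the three cross-method Pearson
#' correlations between PSVG and spectrum width over the rows where MF-DFA
#' is present -- pooled over both states (`r_all`), meditation only
#' (`r_med`) and pre-meditation only (`r_pre`). Correlations are `NA` when
#' fewer than 3 usable rows remain or a variance degenerates.
#'
#' @param comparisons a list of `subject_comparison` rows (or a single
#'   data.frame with the same columns; a `group` column is honoured and
#'   otherwise defaults to `"all"`).
#' @return An object of class `comparison_table`: list with `rows`
#'   (data.frame), `correlations` (named list: `r_all`, `r_med`, `r_pre`),
#'   `group_summary` (data.frame: per group, min/max percent increases of
#'   lambda and width, mean lambda per state).
#' @export
build_table <- function(comparisons) {
  rows <- if (is.data.frame(comparisons)) {
    comparisons
  } else {
    do.call(rbind, lapply(comparisons, as.data.frame))
  }
  if (nrow(rows) < 1L) stop("need at least one comparison", call. = FALSE)
  if (is.null(rows$group)) rows$group <- "all"
  if (is.null(rows$pct_increase_lambda)) {
    rows$pct_increase_lambda <- percent_increase(rows$lambda_pre,
                                                 rows$lambda_med)
  }
  if (is.null(rows$pct_increase_width)) {
    rows$pct_increase_width <- ifelse(
      is.na(rows$width_pre) | rows$width_pre <= 0, NA_real_,
      percent_increase(rows$width_pre, rows$width_med)
    )
  }

  has_w <- !is.na(rows$width_med) & !is.na(rows$width_pre)
  safe_pearson <- function(xs, ys) {
    if (length(xs) < 3L || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(NA_real_)
    }
    pearson(xs, ys)
  }
  correlations <- list(
    r_all = safe_pearson(c(rows$lambda_med[has_w], rows$lambda_pre[has_w]),
                         c(rows$width_med[has_w], rows$width_pre[has_w])),
    r_med = safe_pearson(rows$lambda_med[has_w], rows$width_med[has_w]),
    r_pre = safe_pearson(rows$lambda_pre[has_w], rows$width_pre[has_w])
  )

  group_summary <- do.call(rbind, lapply(split(rows, rows$group), function(g) {
    pw <- g$pct_increase_width[!is.na(g$pct_increase_width)]
    data.frame(
      group = g$group[1L],
      n_subjects = nrow(g),
      min_pct_lambda = min(g$pct_increase_lambda),
      max_pct_lambda = max(g$pct_increase_lambda),
      min_pct_width = if (length(pw)) min(pw) else NA_real_,
      max_pct_width = if (length(pw)) max(pw) else NA_real_,
      mean_lambda_med = mean(g$lambda_med),
      mean_lambda_pre = mean(g$lambda_pre),
      stringsAsFactors = FALSE
    )
  }))
  rownames(group_summary) <- NULL

  structure(
    list(rows = rows, correlations = correlations,
         group_summary = group_summary),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d subjects\n", nrow(x$rows)))
  print(x$rows, row.names = FALSE, digits = 4)
  cr <- x$correlations
  cat(sprintf(
    "cross-method Pearson r: pooled %.3f, meditation %.3f, pre %.3f\n",
    cr$r_all, cr$r_med, cr$r_pre
  ))
  invisible(x)
}
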