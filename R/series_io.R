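#' Read a BPM time-series text file
#'
#' Parses the plain-text dialect used by the PhysioNet meditation heart-rate
#' distribution: whitespace-delimited rows of `(elapsed_seconds, bpm)` or a
#' single column of BPM values; lines starting with `#` are comments.
#'
#' Instantaneous heart rate is unevenly sampled; both analyses in this
#' package deliberately ignore that and treat the series as an ordered
#' sample sequence, so times are carried as metadata only.
#'
#' @param path file path.
#' @param label label to attach to the series (defaults to the file name).
#' @param positive require all values > 0 (the BPM convention). Set to
#'   `FALSE` when reading synthetic series in the same dialect, which may be
#'   negative.
#' @return An [hrv_series].
#' @export
read_bpm_series <- function(path, label = basename(path), positive = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty series file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(fields)
  if (any(ncols > 2L)) {
    stop("line ", line_no[which(ncols > 2L)[1L]],
         ": expected 1 or 2 columns", call. = FALSE)
  }
  two_col <- all(ncols == 2L)
  if (!two_col && !all(ncols == 1L)) {
    stop("line ", line_no[which(ncols != ncols[1L])[1L]],
         ": inconsistent column count", call. = FALSE)
  }
  nums <- suppressWarnings(lapply(fields, as.numeric))
  bad <- vapply(nums, anyNA, logical(1L))
  if (any(bad)) {
    stop("line ", line_no[which(bad)[1L]], ": non-numeric value",
         call. = FALSE)
  }
  if (two_col) {
    times <- vapply(nums, `[`, numeric(1L), 1L)
    values <- vapply(nums, `[`, numeric(1L), 2L)
    if (any(diff(times) <= 0)) {
      stop("line ", line_no[which(diff(times) <= 0)[1L] + 1L],
           ": time stamps not strictly increasing", call. = FALSE)
    }
  } else {
    times <- NULL
    values <- vapply(nums, `[`, numeric(1L), 1L)
  }
  if (!all(is.finite(values))) {
    stop("line ", line_no[which(!is.finite(values))[1L]],
         ": non-finite value", call. = FALSE)
  }
  if (positive && any(values <= 0)) {
    stop("line ", line_no[which(values <= 0)[1L]],
         ": non-positive BPM value", call. = FALSE)
  }
  hrv_series(values, times = times, label = label)
}

#' Write a series in the two-column text dialect
#'
#' Inverse of [read_bpm_series()]: writes `(time, value)` rows, using the
#' sample index when the series has no time stamps. Round-trips to within
#' formatting precision (15 significant digits).
#'
#' @param series an [hrv_series] or numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bpm_series <- function(series, path) {
  x <- series_values(series)
  t <- if (inherits(series, "hrv_series") && !is.null(series$times)) {
    series$times
  } else {
    seq_along(x)
  }
  writeLines(
    sprintf("%.15g %.15g", t, x),
    path
  )
  invisible(path)
}

#' Write an analysis result to CSV or JSON
#'
#' Generic serialiser for the package's result objects. JSON output carries
#' a `schema` field naming the object kind and version. CSV output is
#' defined for `mfdfa_result` (the Fq(s) surface in long form), `psvg_fit`
#' (the degree distribution) and `comparison_table` (one row per subject,
#' columns `subject, lambda_med, lambda_pre, width_med, width_pre,
#' shuffled_width_med, shuffled_width_pre`).
#'
#' @param result an `mfdfa_result`, `psvg_fit`, `visibility_graph` or
#'   `comparison_table`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "csv")) {
  UseMethod("write_result")
}

result_json <- function(schema, payload, path) {
  jsonlite::write_json(
    c(list(schema = schema, schema_version = "1"), payload),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @export
write_result.mfdfa_result <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      label = result$label,
      q_grid = result$q_grid,
      scale_grid = result$scale_grid,
      fq_surface = unname(apply(result$fq_surface, 1L, identity,
                                simplify = FALSE)),
      hurst_q = result$hurst_q,
      tau_q = result$tau_q,
      alpha = result$spectrum$alpha,
      f_alpha = result$spectrum$f_alpha,
      width = result$width,
      order = result$config$order
    )
    return(result_json("mfdfa_result", payload, path))
  }
  long <- expand.grid(q = result$q_grid, s = result$scale_grid,
                      KEEP.OUT.ATTRS = FALSE)
  long$fq <- as.vector(result$fq_surface)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_result.psvg_fit <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    return(result_json("psvg_fit", unclass(result), path))
  }
  utils::write.csv(
    data.frame(k = result$k_values, p_k = result$p_k),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @export
write_result.visibility_graph <- function(result, path,
                                          format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      n_nodes = result$n_nodes,
      edges = unname(apply(result$edges, 1L, identity, simplify = FALSE)),
      degrees = result$degrees
    )
    return(result_json("visibility_graph", payload, path))
  }
  utils::write.csv(
    data.frame(node_i = result$edges[, 1L], node_j = result$edges[, 2L]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @export
write_result.comparison_table <- function(result, path,
                                          format = c("json", "csv")) {
  format <- match.arg(format)
  cols <- c("subject", "lambda_med", "lambda_pre", "width_med", "width_pre",
            "shuffled_width_med", "shuffled_width_pre")
  if (format == "csv") {
    utils::write.csv(result$rows[, cols, drop = FALSE], path,
                     row.names = FALSE)
    return(invisible(path))
  }
  payload <- list(
    rows = result$rows,
    correlations = result$correlations,
    group_summary = result$group_summary
  )
  result_json("comparison_table", payload, path)
}

#' Published meditation study parameters
#'
#' Published PSVG exponents and MF-DFA spectrum widths (original and
#' shuffled-surrogate) for the twelve PhysioNet meditation-database
#' subjects: C1--C8 (Chi meditation) and Y1--Y4 (Kundalini Yoga), each in
#' the pre-meditation and meditation state. MF-DFA widths for the Kundalini
#' group are absent (`NA`): those recordings are too short for a reliable
#' multifractal width, so only the visibility-graph exponent is reported
#' for them.
#'
#' These printed values are inputs to the summary statistics in this
#' package (percent-increase ranges, cross-method correlations); the
#' underlying heart-rate recordings themselves are not redistributed here.
#'
#' @return data.frame with columns `subject`, `group` (`"chi"` or
#'   `"kundalini"`), `lambda_med`, `lambda_pre`, `width_med`, `width_pre`,
#'   `shuffled_width_med`, `shuffled_width_pre`.
#' @export
published_meditation_values <- function() {
  path <- system.file("extdata", "meditation_published_values.csv",
                      package = "hrvfractal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
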