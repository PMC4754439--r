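#' Construct a time series object
#'
#' Light container for an ordered sequence of real-valued samples, optionally
#' carrying time stamps (seconds) and a label such as a subject id and state.
#' Both analyses in this package (MF-DFA and visibility graphs) treat the
#' series as an ordered sample sequence; time stamps are metadata only and
#' never enter the computation.
#'
#' @param values numeric vector of samples (BPM or arbitrary units), length
#'   at least 2, all finite.
#' @param times optional numeric vector of time stamps in seconds, strictly
#'   increasing, same length as `values`.
#' @param label free-text label (e.g. `"C1 meditation"`).
#' @return An object of class `hrv_series`: a list with elements `values`,
#'   `times` (possibly `NULL`) and `label`.
#' @examples
#' ts <- hrv_series(c(71.2, 69.5, 70.1), times = c(0, 0.8, 1.6))
#' length(ts)
#' @export
hrv_series <- function(values, times = NULL, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a time series needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all series values must be finite", call. = FALSE)
  }
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(values)) {
      stop("`times` must have the same length as `values`", call. = FALSE)
    }
    if (any(diff(times) <= 0)) {
      stop("`times` must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(values = values, times = times, label = as.character(label)[1L]),
    class = "hrv_series"
  )
}

# Accept either a bare numeric vector or an hrv_series and return the values.
series_values <- function(series) {
  if (inherits(series, "hrv_series")) return(series$values)
  v <- as.numeric(series)
  if (length(v) < 2L || !all(is.finite(v))) {
    stop("series must be numeric, finite, length >= 2", call. = FALSE)
  }
  v
}

#' @export
length.hrv_series <- function(x) length(x$values)

#' @export
print.hrv_series <- function(x, ...) {
  cat(sprintf(
    "<hrv_series> %d samples%s%s\n",
    length(x$values),
    if (nzchar(x$label)) paste0(", label: ", x$label) else "",
    if (!is.null(x$times)) {
      sprintf(", t = [%.6g, %.6g] s", x$times[1L], x$times[length(x$times)])
    } else ""
  ))
  cat(sprintf(
    "  values: mean %.4g, range [%.4g, %.4g]\n",
    mean(x$values), min(x$values), max(x$values)
  ))
  invisible(x)
}
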