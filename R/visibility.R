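#' Natural visibility graph of a time series
#'
#' Maps a series to an undirected graph with one node per sample. Samples
#' \eqn{X_m} and \eqn{X_n} (m < n) are connected iff every intermediate
#' sample lies strictly below the straight line joining them:
#' \deqn{X_t < X_n + \frac{n - t}{n - m}\,(X_m - X_n)
#'       \quad \text{for all } m < t < n.}
#' The inequality is strict, so a collinear intermediate point blocks
#' visibility; ties break toward fewer edges. Adjacent samples always see
#' each other, so the graph contains the path 1--2--...--n and every node
#' has degree >= 1 (interior nodes >= 2).
#'
#' The criterion compares slopes only, hence the graph is invariant under
#' adding any constant to the whole series. The conventional shift of the
#' series into the positive half-plane is available via `shift_positive`
#' and provably never changes the graph.
#'
#' @param series an [hrv_series] or numeric vector, length >= 2, finite.
#' @param shift_positive if `TRUE`, the series is first shifted so its
#'   minimum is 1. A no-op for the visibility criterion; retained as an
#'   explicit preprocessing step.
#' @return An object of class `visibility_graph`: list with `n_nodes`,
#'   `edges` (2-column matrix of 1-based node pairs, i < j) and `degrees`
#'   (integer vector per node).
#' @examples
#' g <- build_visibility_graph(c(3, 1, 2))
#' g$degrees  # 2 2 2: the valley at sample 2 hides nothing
#' @export
build_visibility_graph <- function(series, shift_positive = FALSE) {
  x <- series_values(series)
  if (isTRUE(shift_positive)) x <- x - min(x) + 1
  edges <- .vg_edges_cpp(x)
  degrees <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = length(x))
  structure(
    list(n_nodes = length(x), edges = edges, degrees = degrees),
    class = "visibility_graph"
  )
}

#' @export
print.visibility_graph <- function(x, ...) {
  cat(sprintf(
    "<visibility_graph> %d nodes, %d edges, mean degree %.3f, max degree %d\n",
    x$n_nodes, nrow(x$edges), mean(x$degrees), max(x$degrees)
  ))
  invisible(x)
}

#' Degree distribution of a visibility graph
#'
#' Empirical \eqn{P(k) = n_k / n} over the degrees that actually occur
#' (zero-frequency degrees are omitted: they carry no information and their
#' log is undefined in the power-law fit).
#'
#' @param graph a `visibility_graph` from [build_visibility_graph()].
#' @return data.frame with columns `k` (degree) and `p_k` (relative
#'   frequency, summing to 1).
#' @export
degree_distribution <- function(graph) {
  stopifnot(inherits(graph, "visibility_graph"))
  tab <- table(graph$degrees)
  out <- data.frame(
    k = as.integer(names(tab)),
    p_k = as.numeric(tab) / graph$n_nodes
  )
  attr(out, "n_nodes") <- graph$n_nodes
  out
}

#' Fit the PSVG exponent to a degree distribution
#'
#' The scale-freeness exponent \eqn{\lambda_p} of the power law
#' \eqn{P(k) \propto k^{-\lambda_p}} is estimated as the ordinary
#' least-squares gradient of \eqn{\log_2 P(k)} against \eqn{\log_2(1/k)}
#' over the fitted degree range; the intercept absorbs the normalisation,
#' and an exact power law with exponent \eqn{\lambda} returns
#' \eqn{+\lambda} with \eqn{R^2 = 1}.
#'
#' The fit window matters: the smallest degrees are geometry-dominated (the
#' two boundary nodes have no left/right neighbours, and every interior node
#' has degree >= 2 from the sequential path regardless of fractality), while
#' the largest degrees are a noisy singleton tail (many distinct degrees
#' observed exactly once, all at P(k) = 1/n, which flattens a log-log
#' regression). The window is therefore an explicit, reported choice. The
#' default uses every observed degree; `auto_range = TRUE` restricts to
#' `k >= 4` and caps at the largest degree observed at least twice, which is
#' the window used for Hurst-exponent recovery on fractional Brownian
#' motion.
#'
#' @param distribution data.frame with columns `k`, `p_k` (from
#'   [degree_distribution()]).
#' @param k_min,k_max optional fit-range bounds on the degree; explicit
#'   bounds override `auto_range` on that side.
#' @param auto_range if `TRUE`, apply the automatic fit window described
#'   above.
#' @return An object of class `psvg_fit`: list with `lambda_p`, `se`,
#'   `r_squared`, `fit_range` (c(k_min, k_max) actually used), `k_values`,
#'   `p_k`, `n_fit` (number of support points used).
#' @export
fit_psvg <- function(distribution, k_min = NULL, k_max = NULL,
                     auto_range = FALSE) {
  stopifnot(is.data.frame(distribution),
            all(c("k", "p_k") %in% names(distribution)))
  if (isTRUE(auto_range)) {
    n_nodes <- attr(distribution, "n_nodes")
    if (is.null(n_nodes)) {
      n_nodes <- round(1 / min(distribution$p_k[distribution$p_k > 0]))
    }
    if (is.null(k_min)) k_min <- 4L
    if (is.null(k_max)) {
      multi <- distribution$k[distribution$p_k >= 2 / n_nodes - 1e-12]
      if (length(multi) && max(multi) > k_min) k_max <- max(multi)
    }
  }
  keep <- distribution$p_k > 0
  if (!is.null(k_min)) keep <- keep & distribution$k >= k_min
  if (!is.null(k_max)) keep <- keep & distribution$k <= k_max
  d <- distribution[keep, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("degree support too small for PSVG (need >= 3 distinct degrees)",
         call. = FALSE)
  }
  fit <- ols_fit(log2(1 / d$k), log2(d$p_k))
  structure(
    list(
      lambda_p = fit$slope,
      se = fit$se,
      r_squared = fit$r_squared,
      fit_range = range(d$k),
      k_values = distribution$k,
      p_k = distribution$p_k,
      n_fit = nrow(d)
    ),
    class = "psvg_fit"
  )
}

#' @export
print.psvg_fit <- function(x, ...) {
  cat(sprintf(
    "<psvg_fit> lambda_p = %.4f (se %.4f, R^2 %.3f) over k in [%d, %d] (%d points)\n",
    x$lambda_p, x$se, x$r_squared, x$fit_range[1L], x$fit_range[2L], x$n_fit
  ))
  invisible(x)
}

#' PSVG exponent of a series
#'
#' Convenience chain: visibility graph, degree distribution, power-law fit.
#' Deterministic. Reliable for series as short as a few hundred samples,
#' which is what makes the visibility-graph route attractive for short
#' physiological recordings where MF-DFA is starved of scales.
#'
#' @inheritParams build_visibility_graph
#' @inheritParams fit_psvg
#' @return A `psvg_fit` (see [fit_psvg()]).
#' @examples
#' bpm <- generate_bpm_like(n = 800, seed = 11)
#' psvg_of_series(bpm)
#' @export
psvg_of_series <- function(series, k_min = NULL, k_max = NULL,
                           auto_range = FALSE, shift_positive = FALSE) {
  g <- build_visibility_graph(series, shift_positive = shift_positive)
  fit_psvg(degree_distribution(g), k_min = k_min, k_max = k_max,
           auto_range = auto_range)
}
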