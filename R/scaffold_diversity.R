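# CSR curves, AUC, P50, and scaled Shannon entropy from scaffold counts.

# Scaffolds sorted by descending count, ties broken by lexicographic key so
# every derived quantity is deterministic.
#' @noRd
sorted_counts <- function(sc) {
  stopifnot(inherits(sc, "ScaffoldCounts"))
  ord <- order(-sc$counts, names(sc$counts), method = "radix")
  sc$counts[ord]
}

#' Cyclic system retrieval (CSR) curve
#'
#' Scaffolds are ranked by descending frequency; the curve plots the
#' cumulative percentage of compounds retrieved (y) against the cumulative
#' percentage of scaffolds considered (x), with the origin prepended. A
#' curve hugging the diagonal signals high scaffold diversity; a curve that
#' shoots up early signals that few scaffolds dominate the library.
#'
#' Two summary metrics are derived: `auc`, the trapezoidal area under the
#' curve on unit-normalized axes (0.5 = maximally diverse, 1 = all
#' compounds share one scaffold), and `p50`, the percentage of scaffolds
#' needed to retrieve 50% of compounds, computed by linear interpolation of
#' the first crossing of y = 50.
#'
#' @param sc a `ScaffoldCounts` object (see [scaffold_counts()]).
#' @return A `CSRCurve` object: list with `points` (data.frame
#'   `pct_scaffolds`, `pct_compounds`), `auc`, `p50`, `library_name`.
#' @export
csr_curve <- function(sc) {
  cnt <- sorted_counts(sc)
  if (!length(cnt)) stop("empty scaffold counts")
  N <- length(cnt)
  M <- sum(cnt)
  x <- c(0, 100 * seq_len(N) / N)
  y <- c(0, 100 * cumsum(as.numeric(cnt)) / M)
  # trapezoidal rule on [0,1]-normalized axes
  auc <- sum(diff(x / 100) * (utils::head(y, -1) + y[-1]) / 200)
  i <- which(y >= 50)[1]
  p50 <- if (y[i] == 50 || i == 1L) x[i] else {
    x[i - 1] + (50 - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
  }
  structure(
    list(points = data.frame(pct_scaffolds = x, pct_compounds = y),
         auc = auc, p50 = p50, library_name = sc$library_name),
    class = "CSRCurve")
}

#' @export
print.CSRCurve <- function(x, ...) {
  cat(sprintf("<CSRCurve> %s: %d points, AUC=%.3f, P50=%.3f%%\n",
              x$library_name, nrow(x$points), x$auc, x$p50))
  invisible(x)
}

#' Scaled Shannon entropy over the most populated scaffolds
#'
#' For the top `n` scaffolds (by count, ties broken lexicographically)
#' holding `P` compounds in total, the Shannon entropy is
#' `SE = -sum(p_i * log2(p_i))` with `p_i = c_i / P`, and the scaled
#' Shannon entropy is `SSE = SE / log2(n)`. SSE is 1 when the compounds
#' are spread evenly across the top scaffolds and 0 when a single scaffold
#' holds them all.
#'
#' If the library has fewer than `n` scaffolds, all of them are used but
#' the normalization stays `log2(n)`; the result carries attribute
#' `truncated = TRUE` in that case.
#'
#' @param sc a `ScaffoldCounts` object.
#' @param n number of top scaffolds (>= 2).
#' @return SSE value in `[0, 1]`.
#' @export
sse <- function(sc, n) {
  if (n < 2) stop("n must be >= 2")
  cnt <- sorted_counts(sc)
  top <- utils::head(cnt, n)
  P <- sum(top)
  p <- as.numeric(top) / P
  p <- p[p > 0]
  se <- abs(-sum(p * log2(p)))   # abs() folds IEEE -0 to 0
  out <- se / log2(n)
  if (length(cnt) < n) attr(out, "truncated") <- TRUE
  out
}

#' SSE profile across a grid of top-n values
#'
#' @param sc a `ScaffoldCounts` object.
#' @param n_grid integer vector of top-n values.
#' @return data.frame with columns `n`, `P` (compounds covered), `sse`.
#' @export
sse_profile <- function(sc, n_grid = c(5, 10, 20, 30, 40, 50, 60, 70)) {
  cnt <- sorted_counts(sc)
  data.frame(
    n = n_grid,
    P = vapply(n_grid, function(n) sum(utils::head(cnt, n)), numeric(1)),
    sse = vapply(n_grid, function(n) as.numeric(sse(sc, n)), numeric(1)))
}

#' Scaffold diversity summary of a library
#'
#' One row with the census counts, their ratios, and the CSR metrics: `M`
#' (library size), `N` (distinct scaffolds, pseudo-scaffold included),
#' `N_sing` (singleton scaffolds), `N/M`, `N_sing/M`, `N_sing/N`, `AUC`,
#' `P50`. Ratios are kept at full precision; round at presentation time.
#'
#' @param sc a `ScaffoldCounts` object.
#' @return one-row data.frame.
#' @export
diversity_summary <- function(sc) {
  stopifnot(inherits(sc, "ScaffoldCounts"))
  curve <- csr_curve(sc)
  data.frame(
    library = sc$library_name,
    M = sc$M,
    N = sc$N,
    N_sing = sc$N_sing,
    N_over_M = sc$N / sc$M,
    Nsing_over_M = sc$N_sing / sc$M,
    Nsing_over_N = sc$N_sing / sc$N,
    AUC = curve$auc,
    P50 = curve$p50,
    stringsAsFactors = FALSE)
}
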