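# Figure builders: CSR overlays, top-scaffold frequency bars, triangular
# heatmaps of library distances, consensus diversity plots, and embedding
# overlays. All return ggplot objects; saving is left to the caller (the
# report writer uses pdf devices).

#' Overlaid CSR curves for several libraries
#'
#' @param curves list of `CSRCurve` objects (see [csr_curve()]).
#' @return a ggplot object; the dashed diagonal marks maximal scaffold
#'   diversity.
#' @export
plot_csr <- function(curves) {
  if (inherits(curves, "CSRCurve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    cbind(cv$points, library = cv$library_name)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$pct_scaffolds, .data$pct_compounds,
                                   color = .data$library)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "% of scaffolds", y = "% of compounds",
                  color = "library") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Frequency bar chart of the most populated scaffolds
#'
#' @param sc a `ScaffoldCounts` object.
#' @param top_n number of scaffolds to show (default 70).
#' @return a ggplot object (scaffold rank vs molecule count).
#' @export
plot_scaffold_frequencies <- function(sc, top_n = 70) {
  cnt <- sorted_counts(sc)
  k <- min(top_n, length(cnt))
  df <- data.frame(rank = seq_len(k), count = as.integer(cnt[seq_len(k)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = sc$library_name,
                  x = sprintf("scaffold rank (top %d)", k),
                  y = "number of molecules") +
    ggplot2::theme_minimal()
}

#' Triangular heatmap plot (THP) of a library distance matrix
#'
#' Lower triangle plus diagonal; intra-library cells (diagonal) are drawn
#' in a red gradient, inter-library cells in a blue gradient, with darker
#' shades meaning larger distances.
#'
#' @param ldm a `LibraryDistanceMatrix` (see [distance_matrix()]).
#' @return a ggplot object.
#' @export
plot_thp <- function(ldm) {
  stopifnot(inherits(ldm, "LibraryDistanceMatrix"))
  m <- ldm$matrix
  nms <- ldm$library_names
  k <- length(nms)
  cells <- do.call(rbind, lapply(seq_len(k), function(i) {
    do.call(rbind, lapply(seq_len(i), function(j) {
      data.frame(row = i, col = j, value = m[i, j], intra = i == j)
    }))
  }))
  cells$row_f <- factor(nms[cells$row], levels = nms)
  cells$col_f <- factor(nms[cells$col], levels = nms)
  rng <- range(cells$value)
  scale01 <- function(v) if (diff(rng) == 0) 0.5 else (v - rng[1]) / diff(rng)
  cells$fill <- ifelse(
    cells$intra,
    grDevices::rgb(1, 1 - 0.8 * scale01(cells$value),
                   1 - 0.8 * scale01(cells$value)),
    grDevices::rgb(1 - 0.8 * scale01(cells$value),
                   1 - 0.8 * scale01(cells$value), 1))
  ggplot2::ggplot(cells, ggplot2::aes(.data$col_f, .data$row_f)) +
    ggplot2::geom_tile(ggplot2::aes(fill = I(.data$fill)), color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(nms)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("library distances (%s)", ldm$metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Consensus diversity plot
#'
#' Quadrant backgrounds follow the conventional coloring: I cyan, II white,
#' III yellow, IV salmon; points are sized by library size and colored on a
#' pink-to-purple gradient by property-based intra-library distance.
#'
#' @param cdp data.frame from [assemble_cdp()].
#' @return a ggplot object.
#' @export
plot_cdp <- function(cdp) {
  xt <- attr(cdp, "x_threshold")
  yt <- attr(cdp, "y_threshold")
  xr <- range(c(cdp$intra_soergel, xt))
  xr <- xr + c(-0.05, 0.05) * max(diff(xr), 0.1)
  yr <- range(c(cdp$auc, yt))
  yr <- yr + c(-0.05, 0.05) * max(diff(yr), 0.1)
  quads <- data.frame(
    xmin = c(xt, xr[1], xr[1], xt),
    xmax = c(xr[2], xt, xt, xr[2]),
    ymin = c(yt, yt, yr[1], yr[1]),
    ymax = c(yr[2], yr[2], yt, yt),
    fill = c("#c9f5f5", "#ffffff", "#fdf6c4", "#fbcfc0"))
  ggplot2::ggplot(cdp) +
    ggplot2::geom_rect(data = quads,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = I(.data$fill))) +
    ggplot2::geom_point(ggplot2::aes(.data$intra_soergel, .data$auc,
                                     size = .data$M,
                                     color = .data$intra_euclid)) +
    ggplot2::geom_text(ggplot2::aes(.data$intra_soergel, .data$auc,
                                    label = .data$library),
                       vjust = -1.1, size = 3) +
    ggplot2::scale_color_gradient(low = "#ffc0e0", high = "#5a0a8c") +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(x = "intra-library Soergel distance (MACCS)",
                  y = "AUC of CSR curve",
                  color = "property\ndistance", size = "library size") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2D chemical-space embedding
#'
#' @param emb an `EmbeddingResult` from [fit_pca()] or [fit_gtm()].
#' @return a ggplot object, one color per library label.
#' @export
plot_embedding <- function(emb) {
  df <- data.frame(dim1 = emb$coords[, 1], dim2 = emb$coords[, 2],
                   library = emb$labels %||% "all")
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   color = .data$library)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(title = emb$method, x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}
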