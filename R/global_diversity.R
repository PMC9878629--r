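# Consensus diversity plot (CDP) assembly: four diversity attributes per
# library condensed into one 2D summary with quadrant labels.

#' Assemble consensus diversity plot data
#'
#' Each library becomes one point: x = Soergel-based intra-library distance
#' on MACCS fingerprints (fingerprint diversity), y = AUC of the CSR curve
#' (scaffold diversity; lower = more diverse), color value = Euclidean
#' property-based intra-library distance, marker size = library size M.
#'
#' The plane is partitioned into four quadrants by x-threshold = median of
#' the intra-library Soergel distances over the plotted libraries and
#' y-threshold = `auc_threshold` (default 0.75):
#'
#' * quadrant IV: `x >= median` and `y <= 0.75` - diverse by both scaffolds
#'   and fingerprints;
#' * quadrant I: `x >= median`, `y > 0.75` - high fingerprint diversity;
#' * quadrant III: `x < median`, `y <= 0.75` - high scaffold diversity;
#' * quadrant II: `x < median`, `y > 0.75` - comparatively low diversity.
#'
#' Boundary ties are assigned to the higher-diversity side (`>= median`,
#' `<= 0.75`), a deterministic rule that avoids discarding diverse
#' libraries.
#'
#' @param summaries data.frame with one row per library and columns
#'   `library`, `intra_soergel`, `auc`, `intra_euclid`, `M`.
#' @param auc_threshold y-axis quadrant threshold (default 0.75).
#' @return data.frame of `CDPPoint`s: input columns plus `quadrant`
#'   (factor: `"I"`, `"II"`, `"III"`, `"IV"`); thresholds stored as
#'   attributes `x_threshold`, `y_threshold`.
#' @export
assemble_cdp <- function(summaries, auc_threshold = 0.75) {
  need <- c("library", "intra_soergel", "auc", "intra_euclid", "M")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  if (nrow(summaries) < 2L) stop("CDP needs at least 2 libraries")
  xt <- stats::median(summaries$intra_soergel)
  hi_x <- summaries$intra_soergel >= xt
  lo_y <- summaries$auc <= auc_threshold
  quadrant <- ifelse(hi_x & lo_y, "IV",
              ifelse(hi_x & !lo_y, "I",
              ifelse(!hi_x & lo_y, "III", "II")))
  out <- summaries
  out$quadrant <- factor(quadrant, levels = c("I", "II", "III", "IV"))
  attr(out, "x_threshold") <- xt
  attr(out, "y_threshold") <- auc_threshold
  out
}

#' Write CDP data as CSV
#'
#' @param cdp data.frame from [assemble_cdp()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cdp <- function(cdp, path) {
  utils::write.csv(cdp, path, row.names = FALSE)
  invisible(path)
}
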