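# Pairwise and library-level distances: Soergel on MACCS fingerprints,
# Euclidean on standardized molecular properties.

#' Soergel distance between two binary fingerprints
#'
#' The Soergel distance is the complement of the Tanimoto coefficient:
#' `d = 1 - |x & y| / |x | y|`. For a pair of all-zero (featureless)
#' vectors the Tanimoto ratio is 0/0; such identical vectors are defined to
#' have distance 0 rather than registering as maximally distant.
#'
#' @param x,y binary vectors of equal length.
#' @return distance in `[0, 1]`.
#' @export
soergel <- function(x, y) {
  if (length(x) != length(y)) stop("fingerprint length mismatch")
  x <- as.logical(x)
  y <- as.logical(y)
  u <- sum(x | y)
  if (u == 0) return(0)
  1 - sum(x & y) / u
}

# All-pairs Soergel distances between the rows of two binary matrices.
# T = AB' / (|A| + |B| - AB'); 0/0 pairs get distance 0.
#' @noRd
soergel_cross <- function(A, B) {
  A <- matrix(as.numeric(A != 0), nrow(A), ncol(A))
  B <- matrix(as.numeric(B != 0), nrow(B), ncol(B))
  common <- tcrossprod(A, B)
  union <- outer(rowSums(A), rowSums(B), "+") - common
  d <- 1 - common / union
  d[union == 0] <- 0
  d
}

# All-pairs Euclidean distances between rows of two (already standardized)
# numeric matrices.
#' @noRd
euclid_cross <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Column means/SDs pooled over a list of property matrices; zero-variance
# columns get SD 1 so they contribute nothing after centering.
#' @noRd
pooled_scale_params <- function(mats) {
  all <- do.call(rbind, mats)
  mu <- colMeans(all)
  sdv <- apply(all, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

#' @noRd
apply_scale <- function(m, sp) {
  sweep(sweep(m, 2, sp$center, "-"), 2, sp$scale, "/")
}

#' @noRd
subsample_rows <- function(m, cap, seed) {
  if (is.null(cap) || nrow(m) <= cap) return(m)
  set.seed(seed)
  m[sort(sample.int(nrow(m), cap)), , drop = FALSE]
}

#' @noRd
check_metric_input <- function(m, metric) {
  if (!is.matrix(m) || nrow(m) < 1L) stop("empty library descriptor set")
  if (metric == "soergel_maccs" && ncol(m) != 166L)
    stop("soergel_maccs expects 166-bit fingerprint matrices")
}

#' Mean inter-library distance
#'
#' The distance between two libraries is the mean pairwise molecular
#' distance over all U x V cross-library pairs, where the per-pair distance
#' is either the Soergel distance on MACCS fingerprints
#' (`metric = "soergel_maccs"`) or the Euclidean distance on z-standardized
#' molecular properties (`metric = "euclid_props"`). For the property
#' metric, each of the six properties is standardized using mean/SD pooled
#' over all molecules taking part in the comparison (or supplied via
#' `scale_params`) so that counts, daltons, and square-angstroms are
#' commensurable.
#'
#' @param A,B descriptor matrices (rows = molecules): fingerprint matrices
#'   from [maccs_fingerprint()] or property matrices from
#'   [property_matrix()].
#' @param metric `"soergel_maccs"` or `"euclid_props"`.
#' @param scale_params optional list with `center` and `scale` vectors for
#'   the property metric (e.g. pooled over a larger set of libraries).
#' @param max_molecules optional cap per library; larger libraries are
#'   subsampled uniformly with `seed` before the exact all-pairs mean.
#' @param seed RNG seed for subsampling (default 1).
#' @return mean distance (scalar).
#' @export
inter_library_distance <- function(A, B,
                                   metric = c("soergel_maccs", "euclid_props"),
                                   scale_params = NULL,
                                   max_molecules = NULL, seed = 1L) {
  metric <- match.arg(metric)
  check_metric_input(A, metric)
  check_metric_input(B, metric)
  A <- subsample_rows(A, max_molecules, seed)
  B <- subsample_rows(B, max_molecules, seed + 1L)
  if (metric == "soergel_maccs") {
    mean(soergel_cross(A, B))
  } else {
    sp <- scale_params %||% pooled_scale_params(list(A, B))
    mean(euclid_cross(apply_scale(A, sp), apply_scale(B, sp)))
  }
}

#' Mean intra-library distance
#'
#' Mean pairwise distance over all unordered distinct molecule pairs within
#' one library (self-pairs excluded, `U(U-1)/2` denominator). Metrics and
#' standardization as in [inter_library_distance()].
#'
#' @inheritParams inter_library_distance
#' @param A descriptor matrix with at least 2 rows.
#' @return mean distance (scalar).
#' @export
intra_library_distance <- function(A,
                                   metric = c("soergel_maccs", "euclid_props"),
                                   scale_params = NULL,
                                   max_molecules = NULL, seed = 1L) {
  metric <- match.arg(metric)
  check_metric_input(A, metric)
  if (nrow(A) < 2L) stop("intra-library distance needs >= 2 molecules")
  A <- subsample_rows(A, max_molecules, seed)
  D <- if (metric == "soergel_maccs") {
    soergel_cross(A, A)
  } else {
    sp <- scale_params %||% pooled_scale_params(list(A))
    As <- apply_scale(A, sp)
    euclid_cross(As, As)
  }
  mean(D[upper.tri(D)])
}

#' Library-level distance matrix
#'
#' Computes the full inter-library distance matrix for a set of libraries
#' under one metric, with intra-library distances on the diagonal (the
#' layout of a triangular heatmap plot). For the property metric, all six
#' properties are z-standardized once with mean/SD pooled over the union of
#' all molecules of all libraries, so every cell of the matrix is on the
#' same scale.
#'
#' @param descriptors named list of descriptor matrices, one per library
#'   (all fingerprints, or all property matrices).
#' @inheritParams inter_library_distance
#' @return A `LibraryDistanceMatrix`: list with `metric`, `library_names`,
#'   `matrix` (symmetric, diagonal = intra-library values), `n_molecules`.
#' @export
distance_matrix <- function(descriptors,
                            metric = c("soergel_maccs", "euclid_props"),
                            max_molecules = NULL, seed = 1L) {
  metric <- match.arg(metric)
  if (length(descriptors) < 2L) stop("need at least 2 libraries")
  nms <- names(descriptors) %||% paste0("lib", seq_along(descriptors))
  for (m in descriptors) check_metric_input(m, metric)
  sp <- if (metric == "euclid_props") pooled_scale_params(descriptors) else NULL
  k <- length(descriptors)
  D <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    D[i, i] <- intra_library_distance(descriptors[[i]], metric,
                                      scale_params = sp,
                                      max_molecules = max_molecules,
                                      seed = seed + i)
    if (i < k) for (j in seq((i + 1), k)) {
      D[i, j] <- D[j, i] <- inter_library_distance(
        descriptors[[i]], descriptors[[j]], metric, scale_params = sp,
        max_molecules = max_molecules, seed = seed + i * k + j)
    }
  }
  structure(
    list(metric = metric, library_names = nms, matrix = D,
         n_molecules = vapply(descriptors, nrow, integer(1))),
    class = "LibraryDistanceMatrix")
}

#' @export
print.LibraryDistanceMatrix <- function(x, ...) {
  cat(sprintf("<LibraryDistanceMatrix> metric=%s, %d libraries\n",
              x$metric, length(x$library_names)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Write a library distance matrix as CSV
#'
#' @param ldm a `LibraryDistanceMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(ldm, path) {
  stopifnot(inherits(ldm, "LibraryDistanceMatrix"))
  utils::write.csv(as.data.frame(ldm$matrix), path, row.names = TRUE)
  invisible(path)
}
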