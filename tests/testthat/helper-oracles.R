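# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, explicit enumeration) so they cannot share a
# bug with the vectorized implementations they check.

oracle_soergel <- function(x, y) {
  stopifnot(length(x) == length(y))
  inter <- 0L
  union <- 0L
  for (i in seq_along(x)) {
    xi <- x[i] != 0
    yi <- y[i] != 0
    if (xi && yi) inter <- inter + 1L
    if (xi || yi) union <- union + 1L
  }
  if (union == 0L) return(0)
  1 - inter / union
}

oracle_inter_mean <- function(A, B, pair_fun) {
  tot <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      tot <- tot + pair_fun(A[i, ], B[j, ])
    }
  }
  tot / (nrow(A) * nrow(B))
}

oracle_intra_mean <- function(A, pair_fun) {
  tot <- 0
  npair <- 0L
  for (i in seq_len(nrow(A) - 1)) {
    for (j in seq(i + 1, nrow(A))) {
      tot <- tot + pair_fun(A[i, ], A[j, ])
      npair <- npair + 1L
    }
  }
  tot / npair
}

oracle_euclid <- function(x, y) sqrt(sum((x - y)^2))

# AUC of the cumulative retrieval curve by explicit per-segment trapezoid
# areas over the descending-sorted counts.
oracle_csr_auc <- function(counts) {
  cnt <- unname(sort(counts, decreasing = TRUE))
  N <- length(cnt)
  M <- sum(cnt)
  x <- seq_len(N) / N
  y <- cumsum(cnt) / M
  area <- x[1] * y[1] / 2
  if (N > 1) {
    for (k in 2:N) {
      area <- area + (x[k] - x[k - 1]) * (y[k] + y[k - 1]) / 2
    }
  }
  area
}

random_fp_matrix <- function(n, p = 166, density = 0.3) {
  matrix(as.integer(stats::runif(n * p) < density), n, p,
         dimnames = list(paste0("m", seq_len(n)),
                         paste0("MACCS", seq_len(p))))
}

write_smiles_fixture <- function(lines) {
  path <- tempfile(fileext = ".smi")
  writeLines(lines, path)
  path
}
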