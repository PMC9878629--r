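# Two-dimensional chemical-space embeddings: PCA and generative topographic
# mapping (GTM) over fingerprint or property matrices.

#' PCA embedding of a descriptor matrix
#'
#' Projects molecules onto the first two principal axes. Features are
#' centered internally; set `scale. = TRUE` for property matrices whose
#' columns live on different scales (binary fingerprints are conventionally
#' left unscaled). Axis signs follow a deterministic convention: the
#' largest-magnitude loading of each axis is made positive, so repeated
#' runs and row-duplicated inputs give identical orientations.
#'
#' @param data numeric matrix, molecules x features (>= 3 rows, >= 2
#'   columns).
#' @param labels optional per-molecule library tags (recycled into the
#'   result for plotting).
#' @param scale. unit-scale columns before the decomposition.
#' @return An `EmbeddingResult`: list with `method = "PCA"`, `coords`
#'   (n x 2 matrix, columns `dim1`, `dim2`), `labels`, `diagnostics`
#'   (list with `explained_variance`, the per-axis variance fractions).
#' @export
fit_pca <- function(data, labels = NULL, scale. = FALSE) {
  data <- as.matrix(data)
  if (nrow(data) < 3L || ncol(data) < 2L)
    stop("PCA needs at least 3 molecules and 2 features")
  if (scale.) {
    sdv <- apply(data, 2, stats::sd)
    data <- data[, sdv > 0, drop = FALSE]
    if (ncol(data) < 2L) stop("fewer than 2 informative features")
  }
  pc <- stats::prcomp(data, center = TRUE, scale. = scale.)
  if (length(pc$sdev) < 2L || pc$sdev[2] < .Machine$double.eps^0.5)
    stop("descriptor matrix has rank < 2; PCA plane is undefined")
  rot <- pc$rotation[, 1:2, drop = FALSE]
  flip <- vapply(1:2, function(k) {
    sign(rot[which.max(abs(rot[, k])), k])
  }, numeric(1))
  coords <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, "*")
  colnames(coords) <- c("dim1", "dim2")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(method = "PCA", coords = coords,
         labels = if (!is.null(labels)) rep_len(labels, nrow(coords)),
         diagnostics = list(explained_variance = ev[1:2])),
    class = "EmbeddingResult")
}

#' @noRd
latent_grid <- function(k) {
  g <- seq(-1, 1, length.out = k)
  as.matrix(expand.grid(dim1 = g, dim2 = g))
}

#' GTM embedding of a descriptor matrix
#'
#' Generative topographic mapping: a regular grid of latent 2D nodes is
#' mapped into descriptor space through a radial-basis-function plus linear
#' mapping, and the mapping, together with a shared Gaussian noise
#' precision `beta`, is fitted by expectation-maximization to maximize the
#' (weight-regularized) data likelihood. Each molecule's embedded
#' coordinate is the responsibility-weighted mean of the latent node
#' positions, so all coordinates lie within the latent square
#' `[-1, 1] x [-1, 1]`.
#'
#' The mapping weights are initialized from the first two principal
#' components, which makes the fit deterministic; `seed` is recorded for
#' provenance and reserved for stochastic extensions. When several
#' libraries are compared, fit one model on the pooled matrix (pass
#' `labels`) rather than one model per library, otherwise the resulting
#' maps are not comparable.
#'
#' @param data numeric matrix, molecules x features (>= 10 rows).
#' @param labels optional per-molecule library tags.
#' @param grid_size latent grid side `k` (k x k nodes; default 16).
#' @param rbf_grid RBF center grid side `m` (m x m centers; default 4).
#' @param rbf_width_factor RBF width as a multiple of the center spacing
#'   (default 0.3).
#' @param regularization Gaussian prior precision on the mapping weights
#'   relative to `beta` (default 0.1).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param seed recorded in diagnostics (fit itself is deterministic).
#' @return An `EmbeddingResult`: `method = "GTM"`, `coords` (posterior-mean
#'   latent positions), `labels`, and `diagnostics` with `log_likelihood`
#'   (per-iteration trace of the penalized objective), `beta`, `converged`,
#'   `n_iter`, `responsibilities` (n x K matrix), `seed`.
#' @export
fit_gtm <- function(data, labels = NULL, grid_size = 16, rbf_grid = 4,
                    rbf_width_factor = 0.3, regularization = 0.1,
                    max_iter = 200, tol = 1e-6, seed = 42) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X)
  D <- ncol(X)
  if (n < 10L) stop("GTM needs at least 10 molecules")
  K <- grid_size^2

  U <- latent_grid(grid_size)                    # K x 2 latent nodes
  C <- latent_grid(rbf_grid)                     # RBF centers
  spacing <- 2 / (rbf_grid - 1)
  sigma <- rbf_width_factor * spacing
  d2 <- outer(rowSums(U^2), rowSums(C^2), "+") - 2 * tcrossprod(U, C)
  Phi <- cbind(exp(-d2 / (2 * sigma^2)), 1)      # K x (m^2 + 1), bias col

  # PCA-based initialization: map the latent grid onto the plane of the
  # first two principal axes, scaled by the component standard deviations.
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(3, D))
  ev <- (sv$d^2) / max(1, (n - 1))               # eigenvalues of covariance
  V <- sv$v
  targets <- sweep(U %*% (t(V[, 1:2, drop = FALSE]) *
                            sqrt(pmax(ev[1:2], .Machine$double.eps))),
                   2, mu, "+")
  lambda0 <- 1e-6
  W <- solve(crossprod(Phi) + lambda0 * diag(ncol(Phi)),
             crossprod(Phi, targets))
  Y <- Phi %*% W
  inter <- as.matrix(stats::dist(Y))
  diag(inter) <- Inf
  beta_inv <- mean(apply(inter, 1, min))^2 / 4
  if (length(ev) >= 3 && is.finite(ev[3])) beta_inv <- max(beta_inv, ev[3])
  beta_inv <- max(beta_inv, 1e-4)
  beta <- 1 / beta_inv

  xsq <- rowSums(X^2)
  loglik <- numeric(0)
  converged <- FALSE
  alpha <- regularization
  R <- NULL
  for (iter in seq_len(max_iter)) {
    ysq <- rowSums(Y^2)
    Dist <- outer(xsq, ysq, "+") - 2 * tcrossprod(X, Y)   # n x K
    A <- -(beta / 2) * Dist                                # log numerators
    amax <- apply(A, 1, max)
    expA <- exp(A - amax)
    rs <- rowSums(expA)
    ll <- sum(amax + log(rs)) + n * (D / 2) * log(beta / (2 * pi)) -
      n * log(K) - (alpha / 2) * sum(W[-nrow(W), ]^2)
    loglik <- c(loglik, ll)
    R <- expA / rs                                         # responsibilities
    if (iter > 1 && abs(ll - loglik[iter - 1]) <
        tol * (abs(ll) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    # M-step: weighted regularized least squares for W, then beta update
    G <- colSums(R)
    reg <- (alpha / beta) * diag(ncol(Phi))
    reg[nrow(reg), ncol(reg)] <- 0                         # bias unpenalized
    W <- solve(crossprod(Phi, Phi * G) + reg, crossprod(Phi, crossprod(R, X)))
    Y <- Phi %*% W
    ysq <- rowSums(Y^2)
    Dist <- outer(xsq, ysq, "+") - 2 * tcrossprod(X, Y)
    beta <- (n * D) / sum(R * Dist)
  }
  if (!converged)
    warning("GTM did not converge within ", max_iter, " iterations")
  coords <- R %*% U
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- rownames(X)
  structure(
    list(method = "GTM", coords = coords,
         labels = if (!is.null(labels)) rep_len(labels, n),
         diagnostics = list(log_likelihood = loglik, beta = beta,
                            converged = converged, n_iter = length(loglik),
                            responsibilities = R, seed = seed)),
    class = "EmbeddingResult")
}

#' @export
print.EmbeddingResult <- function(x, ...) {
  cat(sprintf("<EmbeddingResult> %s: %d molecules\n", x$method,
              nrow(x$coords)))
  if (x$method == "PCA") {
    cat(sprintf("  explained variance: %.3f, %.3f\n",
                x$diagnostics$explained_variance[1],
                x$diagnostics$explained_variance[2]))
  } else {
    cat(sprintf("  %d EM iterations, converged: %s\n",
                x$diagnostics$n_iter, x$diagnostics$converged))
  }
  invisible(x)
}

#' Write embedding coordinates as CSV
#'
#' Columns: `id`, `library`, `dim1`, `dim2`.
#'
#' @param emb an `EmbeddingResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(id = rownames(emb$coords) %||%
                     paste0("mol_", seq_len(nrow(emb$coords))),
                   library = emb$labels %||% NA_character_,
                   dim1 = emb$coords[, 1], dim2 = emb$coords[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
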