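# Classical (Torgerson) multidimensional scaling with rank truncation,
# reconstruction-error reporting, and minimal-dimension search.

#' Classical metric MDS embedding
#'
#' Double-centers the squared distances, `B = -1/2 J D^2 J`, and takes the
#' top `dim` nonnegative eigenpairs of the Gram matrix; coordinates are
#' eigenvectors scaled by the square roots of their eigenvalues. Negative
#' eigenvalues (non-Euclidean noise) are clipped to zero and reported in the
#' diagnostics, not used. Output is canonicalized: eigenvalues descending,
#' and each axis sign-fixed so its largest-magnitude coordinate is positive,
#' making the embedding bit-reproducible.
#'
#' @param D Complete symmetric `dist_matrix`.
#' @param dim Target dimension, `1 <= dim <= n - 1`. If the positive
#'   spectrum is smaller, the effective dimension is reduced with a warning.
#' @return Object of class `embedding`: list with `coords` (n x d labelled
#'   matrix), `dim`, `eigenvalues` (full descending spectrum),
#'   `n_negative_eigenvalues`, `mean_rel_error`, `p95_rel_error`.
#' @export
classical_mds <- function(D, dim) {
  D <- .as_dist_matrix(D)
  if (anyNA(D)) stop("MDS requires a complete distance matrix")
  n <- nrow(D)
  if (dim < 1L || dim > n - 1L) stop("dim must be in [1, n - 1]")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (unclass(D)^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-12
  pos <- which(e$values > tol)
  k <- min(dim, length(pos))
  if (k < dim)
    warning("only ", k, " positive eigenvalue(s); effective dim reduced")
  V <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]
  coords <- V %*% diag(sqrt(lam), k)
  # canonical per-axis sign: largest-|coordinate| entry positive
  for (a in seq_len(k)) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("x", seq_len(k))
  err <- reconstruction_error(D, coords)
  structure(list(coords = coords, dim = k, eigenvalues = e$values,
                 n_negative_eigenvalues = sum(e$values < -tol),
                 mean_rel_error = err[["mean_rel"]],
                 p95_rel_error = err[["p95_rel"]]),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf(
    "<embedding> %d points in %d-D; mean rel. error %.4g, p95 %.4g\n",
    nrow(x$coords), x$dim, x$mean_rel_error, x$p95_rel_error))
  invisible(x)
}

#' Relative reconstruction error of an embedding
#'
#' Compares embedded pairwise distances to the originals as
#' `|dhat_ij - d_ij| / d_ij` over all unordered pairs with `d_ij > 0`
#' (zero-distance pairs are skipped with a warning); reports the mean and
#' the 95th percentile (linear interpolation between order statistics).
#'
#' @param D Original `dist_matrix`.
#' @param coords Embedded coordinates sharing `D`'s labels (or an
#'   `embedding`).
#' @return Named numeric vector `c(mean_rel = , p95_rel = )`.
#' @export
reconstruction_error <- function(D, coords) {
  D <- .as_dist_matrix(D)
  if (inherits(coords, "embedding")) coords <- coords$coords
  coords <- coords[rownames(D), , drop = FALSE]
  Dhat <- as.matrix(stats::dist(coords))
  d <- D[upper.tri(D)]
  dh <- Dhat[upper.tri(Dhat)]
  zero <- d == 0
  if (any(zero)) {
    warning(sum(zero), " zero-distance pair(s) skipped")
    d <- d[!zero]; dh <- dh[!zero]
  }
  rel <- abs(dh - d) / d
  c(mean_rel = mean(rel),
    p95_rel = unname(stats::quantile(rel, 0.95, type = 7)))
}

#' Smallest embedding dimension meeting an error threshold
#'
#' Scans dimensions upward and returns the first whose mean relative
#' reconstruction error is below `mean_error_threshold`. If none below
#' `n - 1` qualifies, returns `n - 1` with a warning.
#'
#' @param D Complete `dist_matrix`.
#' @param mean_error_threshold Mean relative error bound (default 0.02, i.e.
#'   2 percent).
#' @return Integer dimension.
#' @export
min_dimension <- function(D, mean_error_threshold = 0.02) {
  D <- .as_dist_matrix(D)
  n <- nrow(D)
  for (d in seq_len(n - 1L)) {
    emb <- suppressWarnings(classical_mds(D, d))
    if (emb$mean_rel_error < mean_error_threshold) return(d)
  }
  warning("threshold not reached below n - 1; returning n - 1")
  n - 1L
}

#' Write an embedding to CSV (+ JSON diagnostics)
#'
#' @param embedding An `embedding`.
#' @param path Output CSV path (`label,x1..xd`); diagnostics go to
#'   `paste0(path, ".json")`.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(label = rownames(embedding$coords), embedding$coords,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dim = embedding$dim,
         eigenvalues = embedding$eigenvalues,
         n_negative_eigenvalues = embedding$n_negative_eigenvalues,
         mean_rel_error = embedding$mean_rel_error,
         p95_rel_error = embedding$p95_rel_error),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
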