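# Amino-acid distance matrices in complexity space: autoscaling, Euclidean
# distances with missing-pair support, min-max normalization, and matrix
# comparison (Pearson / Spearman / two-sample KS).

#' Autoscale a metrics table
#'
#' Column-wise standardization to zero mean and unit variance (sample
#' standard deviation, n-1) across amino acids. Missing cells stay missing
#' and are excluded from the column moments.
#'
#' @param table A [metrics_table()] or numeric matrix with row/column names.
#' @return A `scaled_matrix`: numeric matrix with columns of mean ~0 and
#'   variance ~1, retaining any `framework` attribute.
#' @export
autoscale <- function(table) {
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat))
    stop("constant (or all-missing) metric column(s): ",
         paste(colnames(m)[flat], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sds, "/")
  structure(out, framework = attr(table, "framework", exact = TRUE),
            class = c("scaled_matrix", "matrix"))
}

#' Euclidean distance matrix over amino acids
#'
#' `d_ij = sqrt(sum_k (x_ik - x_jk)^2)` over metric columns. Missing values
#' are handled per `missing`:
#' * `"mask"` (default): a pair with a missing value in either row for any
#'   column is masked (`NA` distance), mirroring exclusion of incomplete
#'   pairs from downstream comparisons;
#' * `"pairwise"`: each pair uses the columns complete in both rows; masked
#'   only when no shared complete column exists;
#' * `"fail"`: any missing value is an error (main-pipeline setting).
#'
#' @param X A `scaled_matrix` (or any numeric matrix with row names).
#' @param missing One of `"mask"`, `"pairwise"`, `"fail"`.
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal and
#'   `NA` for masked pairs, labelled by the input row names.
#' @export
distance_matrix <- function(X, missing = c("mask", "pairwise", "fail")) {
  missing <- match.arg(missing)
  m <- unclass(as.matrix(X))
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) stop("rows must be labelled")
  if (anyNA(m) && missing == "fail")
    stop("missing metric values present; use missing = \"mask\" or ",
         "\"pairwise\", or complete the table")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (!anyNA(m)) {
    D[] <- as.matrix(stats::dist(m))
  } else {
    incomplete <- rowSums(is.na(m)) > 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (missing == "mask" && (incomplete[i] || incomplete[j])) {
          D[i, j] <- D[j, i] <- NA_real_
        } else {
          ok <- !is.na(m[i, ]) & !is.na(m[j, ])
          D[i, j] <- D[j, i] <-
            if (any(ok)) sqrt(sum((m[i, ok] - m[j, ok])^2)) else NA_real_
        }
      }
    }
  }
  structure(D, class = c("dist_matrix", "matrix"))
}

.as_dist_matrix <- function(D) {
  m <- unclass(as.matrix(D))
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  structure(m, class = c("dist_matrix", "matrix"))
}

#' Min-max normalize a distance matrix
#'
#' Affine map of all unmasked off-diagonal distances, as one pooled
#' population, onto `[0, 1]`: the global minimum maps to 0 and the maximum
#' to 1.
#'
#' @param D A `dist_matrix` (or symmetric labelled matrix).
#' @return A `dist_matrix` of normalized distances.
#' @export
normalize_distances <- function(D) {
  D <- .as_dist_matrix(D)
  off <- D[upper.tri(D)]
  rng <- range(off, na.rm = TRUE)
  if (diff(rng) == 0) stop("all distances equal: cannot min-max normalize")
  out <- (D - rng[1L]) / diff(rng)
  diag(out) <- 0
  structure(out, class = c("dist_matrix", "matrix"))
}

#' Compare two distance matrices
#'
#' Pearson and Spearman correlations over the vectorized upper triangles,
#' restricted to pairs unmasked in both matrices, plus the two-sample
#' Kolmogorov-Smirnov statistic (maximum ECDF difference) between the two
#' distance distributions.
#'
#' @param D1,D2 `dist_matrix` objects over the same label set.
#' @return List with `pearson_r`, `spearman_rho`, `ks_D`, `ks_p`,
#'   `n_pairs_used`, `n_pairs_excluded`.
#' @export
compare_matrices <- function(D1, D2) {
  D1 <- .as_dist_matrix(D1); D2 <- .as_dist_matrix(D2)
  if (!identical(rownames(D1), rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2)))
      stop("distance matrices have different label sets")
    D2 <- D2[rownames(D1), rownames(D1)]
  }
  v1 <- D1[upper.tri(D1)]
  v2 <- D2[upper.tri(D2)]
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3L) stop("fewer than 3 usable pairs")
  ks <- suppressWarnings(stats::ks.test(v1[ok], v2[ok]))
  list(pearson_r = stats::cor(v1[ok], v2[ok]),
       spearman_rho = stats::cor(v1[ok], v2[ok], method = "spearman"),
       ks_D = unname(ks$statistic),
       ks_p = ks$p.value,
       n_pairs_used = sum(ok),
       n_pairs_excluded = sum(!ok))
}

#' Read / write a labelled square distance matrix CSV
#'
#' @param path CSV path; first column holds row labels.
#' @return A `dist_matrix`.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  .as_dist_matrix(as.matrix(df))
}

#' @rdname read_distance_matrix
#' @param D A `dist_matrix`.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.csv(as.matrix(D), path, row.names = TRUE, na = "")
  invisible(path)
}
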