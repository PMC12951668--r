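# Association of chronology scores with amino-acid usage vectors and with
# molecular weight.

#' Free amino-acid molecular weights
#'
#' Monomer (free amino acid) molecular masses in g/mol for the 20 canonical
#' residues.
#'
#' @return Named numeric vector in canonical symbol order.
#' @export
aa_molecular_weights <- function() {
  c(A = 89.09, C = 121.16, D = 133.10, E = 147.13, F = 165.19,
    G = 75.07, H = 155.15, I = 131.17, K = 146.19, L = 131.17,
    M = 149.21, N = 132.12, P = 115.13, Q = 146.15, R = 174.20,
    S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19)
}

#' Ordinary least squares fit of usage on a chronology score
#'
#' Unweighted simple linear regression (a weighted variant is available via
#' `weights`, e.g. inverse squared standard errors). Reports the slope,
#' intercept, `R^2` (the squared Pearson correlation) and the two-sided
#' p-value for the slope on `n - 2` degrees of freedom.
#'
#' @param x Numeric predictor (e.g. root-to-node distance), length >= 3.
#' @param y Numeric response (e.g. proteome usage), same length.
#' @param weights Optional regression weights.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_fit <- function(x, y, weights = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite observations")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  fit <- if (is.null(weights)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = weights[ok])
  s <- summary(fit)
  co <- s$coefficients
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = unname(s$r.squared),
       p_value = unname(co["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Pooled weight-versus-complexity correlation
#'
#' Min-max normalizes each metric column, pools all amino-acid x metric
#' datapoints (20 x 16 = 320 for the full panel) against molecular weight,
#' and returns the squared Pearson correlation. A weak pooled correlation
#' indicates that complexity is not simply a proxy for mass. Constant
#' columns are excluded with a warning.
#'
#' @param table A [metrics_table()] (complete rows are used).
#' @param weights Named molecular weights; defaults to
#'   [aa_molecular_weights()].
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
weight_complexity_r2 <- function(table, weights = aa_molecular_weights()) {
  m <- unclass(as.matrix(table))
  rng <- apply(m, 2L, function(v) diff(range(v, na.rm = TRUE)))
  flat <- !is.finite(rng) | rng == 0
  if (any(flat)) {
    warning("constant metric column(s) excluded: ",
            paste(colnames(m)[flat], collapse = ", "))
    m <- m[, !flat, drop = FALSE]
  }
  norm <- apply(m, 2L, function(v) {
    r <- range(v, na.rm = TRUE); (v - r[1L]) / diff(r)
  })
  w <- weights[rownames(m)]
  x <- rep(w, times = ncol(norm))
  y <- as.vector(norm)
  ok <- is.finite(x) & is.finite(y)
  stats::cor(x[ok], y[ok])^2
}

#' Load an amino-acid usage table from CSV
#'
#' Expects columns `label`, `usage`, and optionally `stderr`.
#'
#' @param path CSV path.
#' @return Data frame with rows for the 20 canonical amino acids in
#'   canonical order, columns `label`, `usage`, `stderr` (NA if absent).
#' @export
load_usage_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("label", "usage")
  if (!"stderr" %in% names(df)) df$stderr <- NA_real_
  bad <- setdiff(df$label, aa_symbols())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(aa_symbols(), df$label)
  if (length(missing))
    stop("usage table missing amino acid(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(df$usage)) || any(df$usage < 0))
    stop("usages must be finite and nonnegative")
  df <- df[match(aa_symbols(), df$label), c("label", "usage", "stderr")]
  rownames(df) <- NULL
  df
}
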