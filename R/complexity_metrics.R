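# Topological complexity indices on hydrogen-suppressed molecular graphs,
# Euclidean-norm composites, and the metrics-table reader for externally
# supplied index values.

#' Construct a hydrogen-suppressed molecular graph
#'
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Two-column matrix or data frame of 1-based atom index pairs;
#'   an optional third column gives bond order (ignored by the topological
#'   indices, which use the simple graph).
#' @param sp3 Logical vector flagging sp3-hybridized carbons (annotation;
#'   perception is out of scope). Default all `FALSE`.
#' @param chiral Logical vector flagging chiral centers. Default all `FALSE`.
#' @return Object of class `molecular_graph` with fields `elements`, `sp3`,
#'   `chiral`, `edges` (m x 2 integer matrix), `n`.
#' @examples
#' propane <- molecular_graph(rep("C", 3), rbind(c(1, 2), c(2, 3)))
#' total_walk_count(propane)
#' @export
molecular_graph <- function(elements, bonds, sp3 = NULL, chiral = NULL) {
  n <- length(elements)
  if (n < 1L) stop("graph must have at least one atom")
  if (is.null(sp3)) sp3 <- rep(FALSE, n)
  if (is.null(chiral)) chiral <- rep(FALSE, n)
  stopifnot(length(sp3) == n, length(chiral) == n)
  bonds <- as.matrix(bonds)
  edges <- matrix(as.integer(bonds[, 1:2, drop = FALSE]), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n))
      stop("bond atom index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loop bond")
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  g <- structure(list(elements = as.character(elements),
                      sp3 = as.logical(sp3), chiral = as.logical(chiral),
                      edges = edges, n = n),
                 class = "molecular_graph")
  if (n > 1L && .n_components_adj(adjacency_matrix(g)) != 1L)
    stop("molecular graph must be connected")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", x$n, "atoms,", nrow(x$edges), "bonds;",
      "formula:", paste(names(table(x$elements)),
                        table(x$elements), collapse = " "), "\n")
  invisible(x)
}

#' Adjacency matrix of a molecular graph
#'
#' @param g A [molecular_graph()].
#' @return n x n symmetric 0/1 matrix.
#' @export
adjacency_matrix <- function(g) {
  A <- matrix(0, g$n, g$n)
  if (nrow(g$edges)) {
    A[g$edges] <- 1
    A[g$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

# Connected components of an adjacency matrix (BFS).
.n_components_adj <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  k
}

#' Total walk count
#'
#' Sum over walk lengths `k = 1..V-1` of the grand total of `A^k` entries of
#' the hydrogen-suppressed adjacency matrix: every walk is counted from each
#' start atom, with no one-half symmetry factor. Grows exponentially with
#' size (2 for the 2-vertex path up to 6500 for the 10-vertex path).
#'
#' @param g A [molecular_graph()] with at least 2 atoms.
#' @return Positive number of walks.
#' @export
total_walk_count <- function(g) {
  if (g$n < 2L) stop("walk count undefined for a single-atom graph")
  A <- adjacency_matrix(g)
  w <- rep(1, g$n)
  total <- 0
  for (k in seq_len(g$n - 1L)) {
    w <- as.vector(A %*% w)
    total <- total + sum(w)
  }
  total
}

#' Log-transformed walk count
#'
#' Base-10 logarithm of [total_walk_count()], compensating for the
#' exponential scaling of walk counts with molecular size. The base is inert
#' downstream: autoscaling removes affine transforms.
#'
#' @inheritParams total_walk_count
#' @return Real value `log10(TWC)`.
#' @export
log_wcx <- function(g) log10(total_walk_count(g))

#' First and second Zagreb indices
#'
#' `M1 = sum(deg^2)` over atoms; `M2 = sum(deg_u * deg_v)` over bonds.
#' Symmetry-modified variants (automorphism-orbit weighting) are an optional
#' extension hook; the plain indices are computed here.
#'
#' @inheritParams total_walk_count
#' @return Named numeric vector `c(M1 = , M2 = )`.
#' @export
zagreb_indices <- function(g) {
  deg <- .degrees(g)
  M2 <- if (nrow(g$edges)) sum(deg[g$edges[, 1L]] * deg[g$edges[, 2L]]) else 0
  c(M1 = sum(deg^2), M2 = M2)
}

.degrees <- function(g) {
  tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$n)
}

# Number of simple paths with 2 edges.
.path2_count <- function(g) sum(choose(.degrees(g), 2))

# Number of simple paths with 3 edges (4 distinct vertices); each path has a
# unique central edge, iterated once.
.path3_count <- function(g) {
  A <- adjacency_matrix(g)
  total <- 0L
  for (e in seq_len(nrow(g$edges))) {
    u <- g$edges[e, 1L]; v <- g$edges[e, 2L]
    nu <- setdiff(which(A[u, ] > 0), v)
    nv <- setdiff(which(A[v, ] > 0), u)
    for (a in nu) total <- total + sum(nv != a)
  }
  total
}

#' Kier kappa shape indices
#'
#' First through third order kappa values from atom count `A` and path counts
#' `P1..P3`: `1k = A(A-1)^2/P1^2`, `2k = (A-1)(A-2)^2/P2^2`, and
#' `3k = (A-1)(A-3)^2/P3^2` for odd `A`, `(A-3)(A-2)^2/P3^2` for even `A`.
#' An index whose path count is zero is undefined and reported `NA`.
#'
#' @inheritParams total_walk_count
#' @return Named numeric vector `c(K1 = , K2 = , K3 = )`, `NA` where
#'   undefined.
#' @export
kappa_indices <- function(g) {
  A <- g$n
  P1 <- nrow(g$edges)
  P2 <- .path2_count(g)
  P3 <- .path3_count(g)
  K1 <- if (P1 > 0) A * (A - 1)^2 / P1^2 else NA_real_
  K2 <- if (P2 > 0) (A - 1) * (A - 2)^2 / P2^2 else NA_real_
  K3 <- if (P3 > 0) {
    if (A %% 2L == 1L) (A - 1) * (A - 3)^2 / P3^2
    else (A - 3) * (A - 2)^2 / P3^2
  } else NA_real_
  c(K1 = K1, K2 = K2, K3 = K3)
}

# All-pairs shortest path distances (unweighted BFS).
.graph_distances <- function(g) {
  A <- adjacency_matrix(g)
  n <- g$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & is.infinite(dist))
      dist[nb] <- dist[v] + 1
      queue <- c(queue, nb)
    }
    D[s, ] <- dist
  }
  D
}

#' Balaban distance-sum connectivity index J
#'
#' `J = m / (mu + 1) * sum_edges (s_u s_v)^(-1/2)`, with `m` the bond count,
#' `mu = m - n + 1` the cyclomatic number, and `s` the row sums of the
#' topological (shortest-path) distance matrix.
#'
#' @inheritParams total_walk_count
#' @return Real index value.
#' @export
balaban_j <- function(g) {
  m <- nrow(g$edges)
  if (m == 0L) stop("Balaban J undefined for an edgeless graph")
  s <- rowSums(.graph_distances(g))
  mu <- m - g$n + 1L
  terms <- 1 / sqrt(s[g$edges[, 1L]] * s[g$edges[, 2L]])
  m / (mu + 1) * sum(terms)
}

#' Fraction of chiral centers and of sp3 carbons
#'
#' `FCC` = flagged chiral-center carbons / carbons; `FSP3` = flagged sp3
#' carbons / carbons. Flags come from the graph's atom annotations;
#' stereo/hybridization perception is out of scope.
#'
#' @inheritParams total_walk_count
#' @return Named numeric vector `c(FCC = , FSP3 = )`, both in `[0, 1]`.
#' @export
fraction_indices <- function(g) {
  carbon <- g$elements == "C"
  nc <- sum(carbon)
  if (nc == 0L) stop("fraction indices require at least one carbon")
  c(FCC = sum(g$chiral & carbon) / nc,
    FSP3 = sum(g$sp3 & carbon) / nc)
}

#' Euclidean-norm composite of index values
#'
#' Combines multi-component indices (e.g. the two modified Zagreb indices or
#' the three kappa indices) into a single value `sqrt(sum(v^2))`. Any missing
#' component makes the composite missing.
#'
#' @param values Numeric vector of component values.
#' @return Real norm, or `NA` if any component is `NA`.
#' @export
euclidean_combine <- function(values) {
  if (anyNA(values)) return(NA_real_)
  sqrt(sum(values^2))
}

#' Compute the in-package index panel for one molecular graph
#'
#' Convenience wrapper returning all indices this package computes from a
#' hydrogen-suppressed graph plus annotations: logWCX, the Euclidean norm of
#' the Zagreb pair (NSMM column placeholder; plain indices unless an orbit
#' hook is supplied), the norm of the kappa triple (NK), Balaban J (BAL),
#' FCC and FSP3.
#'
#' @inheritParams total_walk_count
#' @return Named numeric vector.
#' @export
compute_graph_metrics <- function(g) {
  fr <- fraction_indices(g)
  c(logWCX = log_wcx(g),
    NSMM = euclidean_combine(zagreb_indices(g)),
    NK = euclidean_combine(kappa_indices(g)),
    BAL = balaban_j(g),
    FCC = unname(fr["FCC"]),
    FSP3 = unname(fr["FSP3"]))
}

#' Read a molecular graph from JSON
#'
#' Expects an object with an `atoms` array (each atom an object with
#' `element` and optional logical `sp3`, `chiral`) and a `bonds` array of
#' 1-based index pairs.
#'
#' @param path Path to a JSON file.
#' @return A [molecular_graph()].
#' @export
read_molecular_graph <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  atoms <- spec$atoms
  bonds <- spec$bonds
  if (is.list(bonds) && !is.matrix(bonds)) bonds <- do.call(rbind, bonds)
  molecular_graph(elements = atoms$element,
                  bonds = bonds,
                  sp3 = if (!is.null(atoms$sp3)) atoms$sp3,
                  chiral = if (!is.null(atoms$chiral)) atoms$chiral)
}

# ---- metrics table ---------------------------------------------------------

#' Construct a complexity metrics table
#'
#' A metrics table holds one row per amino acid and one column per complexity
#' metric, each metric tagged with its framework (`"graph"` or
#' `"information"`). Missing values are allowed and preserved.
#'
#' @param values Numeric matrix or data frame with amino-acid one-letter row
#'   names and metric column names.
#' @param framework Named character vector mapping every metric name to
#'   `"graph"` or `"information"`.
#' @param require_full If `TRUE` (default) all 20 canonical amino acids must
#'   be present; subsets are allowed otherwise (toy fixtures).
#' @return Object of class `metrics_table`: numeric matrix with a
#'   `framework` attribute, rows in canonical order.
#' @export
metrics_table <- function(values, framework, require_full = TRUE) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  labs <- rownames(m)
  if (is.null(labs)) stop("metrics table needs amino-acid row names")
  bad <- setdiff(labs, aa_symbols())
  if (length(bad))
    stop("unknown amino-acid row(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(labs))
    stop("duplicate amino-acid row(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (require_full) {
    missing <- setdiff(aa_symbols(), labs)
    if (length(missing))
      stop("metrics table is missing amino acid(s): ",
           paste(missing, collapse = ", "))
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("metric columns must have unique names")
  framework <- framework[colnames(m)]
  if (anyNA(framework) || is.null(names(framework)))
    stop("every metric needs a framework tag (graph/information)")
  bad_tag <- setdiff(unique(framework), c("graph", "information"))
  if (length(bad_tag))
    stop("invalid framework tag(s): ", paste(bad_tag, collapse = ", "))
  m <- m[intersect(aa_symbols(), labs), , drop = FALSE]
  structure(m, framework = framework, class = c("metrics_table", "matrix"))
}

#' @export
print.metrics_table <- function(x, ...) {
  fw <- attr(x, "framework")
  cat("<metrics_table>", nrow(x), "amino acids x", ncol(x), "metrics (",
      sum(fw == "graph"), "graph,", sum(fw == "information"),
      "information );", sum(is.na(x)), "missing value(s)\n")
  print(unclass(structure(x, framework = NULL)), ...)
  invisible(x)
}

#' Subset a metrics table by framework
#'
#' @param table A [metrics_table()].
#' @param framework `"graph"` or `"information"`.
#' @return A [metrics_table()] restricted to that framework's metrics.
#' @export
framework_subset <- function(table, framework = c("graph", "information")) {
  framework <- match.arg(framework)
  fw <- attr(table, "framework")
  keep <- names(fw)[fw == framework]
  if (!length(keep)) stop("no metrics tagged ", framework)
  metrics_table(unclass(table)[, keep, drop = FALSE], fw[keep],
                require_full = FALSE)
}

#' Load a metrics table from CSV
#'
#' The CSV's first column holds amino-acid one-letter symbols; remaining
#' columns are metrics. Framework tags come either from a data row whose
#' symbol cell is `framework` (header convention) or from the `framework`
#' argument (named vector, or path to a two-column `metric,framework` CSV).
#' Empty cells become missing values and are reported, not dropped.
#'
#' @param path CSV path.
#' @param framework Optional named character vector or sidecar CSV path.
#' @inheritParams metrics_table
#' @return A [metrics_table()].
#' @export
load_metrics_table <- function(path, framework = NULL, require_full = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- as.character(df[[1L]])
  fw_row <- which(labs == "framework")
  if (length(fw_row)) {
    tags <- as.character(unlist(df[fw_row[1L], -1L]))
    framework <- stats::setNames(tags, colnames(df)[-1L])
    df <- df[-fw_row, , drop = FALSE]
    labs <- labs[-fw_row]
  } else if (is.character(framework) && length(framework) == 1L &&
             is.null(names(framework)) && file.exists(framework)) {
    side <- utils::read.csv(framework, stringsAsFactors = FALSE)
    framework <- stats::setNames(as.character(side[[2L]]),
                                 as.character(side[[1L]]))
  }
  if (is.null(framework))
    stop("no framework tags: supply a 'framework' row or sidecar")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  non_num <- is.na(vals) & !(is.na(df[, -1L]) | df[, -1L] == "")
  if (any(non_num)) {
    idx <- which(non_num, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", labs[idx[1L]], "', column '",
         colnames(vals)[idx[2L]], "'")
  }
  rownames(vals) <- labs
  metrics_table(vals, framework, require_full = require_full)
}

#' Write a metrics table to CSV (with framework header row)
#'
#' @param table A [metrics_table()].
#' @param path Output CSV path.
#' @export
write_metrics_table <- function(table, path) {
  fw <- attr(table, "framework")
  df <- data.frame(aa = c("framework", rownames(table)),
                   rbind(fw[colnames(table)], unclass(table)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("aa", colnames(table))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
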