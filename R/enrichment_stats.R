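# Mutational-connectivity statistics of a tree: observed per-position
# counts, label-permutation null, path-graph null, and substitution-matrix
# comparison.

.positions <- c("1", "2", "3", "ALL")

# Per-position 20x20 count matrices restricted to a label subset.
.count_mats <- function(labels, code) {
  arr <- .count_array(code)
  lapply(stats::setNames(1:4, .positions), function(p) {
    S <- if (p == 4L) arr[, , 1L] + arr[, , 2L] + arr[, , 3L] else arr[, , p]
    S[labels, labels, drop = FALSE]
  })
}

#' Observed mutation counts along a tree
#'
#' Sums single-point mutation counts `S_{i->j}` over the tree's edges, per
#' codon position and in total. The fraction column follows the documented
#' convention `sum(S) / sum(M_i)` with `i` the edge endpoint nearer the root
#' (the root defaults to the tree's root, else `"G"` when present).
#'
#' @param tree A `spanning_tree` whose labels are canonical amino-acid
#'   symbols.
#' @param code A [codon_table()].
#' @param root Root used for the fraction's denominator orientation; `NA`
#'   fractions if no root is resolvable.
#' @return Data frame with one row per position (`1`, `2`, `3`, `ALL`) and
#'   columns `position`, `observed_count`, `observed_fraction`.
#' @export
tree_mutation_counts <- function(tree, code = default_code(),
                                 root = NULL) {
  bad <- setdiff(tree$labels, aa_symbols())
  if (length(bad))
    stop("non-canonical tree label(s): ", paste(bad, collapse = ", "))
  if (is.null(root))
    root <- if (!is.null(tree$root)) tree$root
            else if ("G" %in% tree$labels) "G" else NA_character_
  mats <- .count_mats(tree$labels, code)
  idx <- cbind(tree$edges$from, tree$edges$to)
  counts <- vapply(mats, function(S) sum(S[idx]), numeric(1L))
  fractions <- rep(NA_real_, 4L)
  if (!is.na(root)) {
    rd <- root_to_node(tree, root)
    near <- ifelse(rd[tree$edges$from] <= rd[tree$edges$to],
                   tree$edges$from, tree$edges$to)
    for (p in 1:4) {
      pos <- if (p == 4L) "ALL" else p
      caps <- vapply(near, mutation_capacity, numeric(1L),
                     position = pos, code = code)
      fractions[p] <- counts[p] / sum(caps)
    }
  }
  data.frame(position = .positions,
             observed_count = unname(counts),
             observed_fraction = fractions,
             stringsAsFactors = FALSE)
}

#' Permutation null for tree mutational connectivity
#'
#' Randomly reassigns amino acids to the tree's nodes (uniform bijections)
#' while keeping the topology fixed, and accumulates per-position mutation
#' totals over `n_trials` trials. Reports the ensemble mean, standard
#' deviation, and the normal-approximation 95% confidence interval
#' `mu +/- 1.96 sigma / sqrt(N)`, plus an enrichment flag (observed count
#' above the CI's upper bound). For the full 20-amino-acid set the
#' expectation is topology-independent and equals
#' `19 * background_per_pair_mean(p)`.
#'
#' @param tree A `spanning_tree` with canonical amino-acid labels.
#' @param n_trials Number of random label assignments (default `1e5`).
#' @param seed Integer seed for reproducibility (recorded in the result).
#' @inheritParams tree_mutation_counts
#' @return Object of class `randomization_result`: data frame with one row
#'   per position (`observed`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `enriched`), with attributes `n_trials` and `seed`.
#' @export
randomize_assignments <- function(tree, n_trials = 1e5, seed = NULL,
                                  code = default_code()) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  bad <- setdiff(tree$labels, aa_symbols())
  if (length(bad))
    stop("non-canonical tree label(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  labs <- tree$labels
  n <- length(labs)
  mats <- .count_mats(labs, code)
  eu <- match(tree$edges$from, labs)
  ev <- match(tree$edges$to, labs)
  perms <- matrix(0L, nrow = n_trials, ncol = n)
  for (t in seq_len(n_trials)) perms[t, ] <- sample.int(n)
  iu <- perms[, eu, drop = FALSE]
  iv <- perms[, ev, drop = FALSE]
  flat <- (iv - 1L) * n + iu   # column-major index into n x n count matrix
  obs <- tree_mutation_counts(tree, code)
  out <- lapply(1:4, function(p) {
    totals <- rowSums(matrix(as.vector(mats[[p]])[flat],
                             nrow = n_trials))
    mu <- mean(totals)
    sdv <- stats::sd(totals)
    half <- 1.96 * sdv / sqrt(n_trials)
    data.frame(position = .positions[p],
               observed = obs$observed_count[p],
               mean = mu, sd = sdv,
               ci_low = mu - half, ci_high = mu + half,
               enriched = obs$observed_count[p] > mu + half,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            n_trials = n_trials, seed = seed,
            class = c("randomization_result", "data.frame"))
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("<randomization_result> N =", attr(x, "n_trials"),
      "label permutations\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Path-graph null expectations
#'
#' Closed-form expected per-position mutation totals of a randomly ordered
#' 20-amino-acid path graph (19 edges): `E(p) = 19 * B(p)` with `B(p)` the
#' per-pair background mean. For the standard code: 8.300, 8.800, 2.500 and
#' 19.600 in total.
#'
#' @inheritParams tree_mutation_counts
#' @return Named numeric vector over positions `1`, `2`, `3`, `ALL`.
#' @export
path_graph_null <- function(code = default_code()) {
  vapply(stats::setNames(.positions, .positions),
         function(p) path_graph_expectation(p, code), numeric(1L))
}

#' Compare a substitution matrix along a tree versus all pairs
#'
#' Mean matrix entry over the tree's edges versus the mean over all
#' unordered amino-acid pairs; a tree preserving mutational proximity has a
#' smaller adjacent mean.
#'
#' @param tree A `spanning_tree`.
#' @param matrix Symmetric numeric matrix labelled by the tree's labels
#'   (e.g. a codon substitution-distance matrix).
#' @return List with `mean_adjacent` and `mean_all`.
#' @export
substitution_matrix_compare <- function(tree, matrix) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m)) || !all(tree$labels %in% rownames(m)))
    stop("matrix must be labelled with the tree's amino acids")
  m <- m[tree$labels, tree$labels]
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("substitution matrix must be symmetric")
  list(mean_adjacent = mean(m[cbind(tree$edges$from, tree$edges$to)]),
       mean_all = mean(m[upper.tri(m)]))
}
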