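# Epsilon-neighborhood (Vietoris-Rips 1-skeleton) graph, Prim's minimum
# spanning tree, root-to-node chronology, rank-based composite order, and
# tree comparison.

#' Build an epsilon-neighborhood graph
#'
#' The 1-skeleton of the Vietoris-Rips complex at scale `eps_total`: an edge
#' joins two amino acids iff their pairwise distance is at most `eps_total`.
#' The threshold is expressed per embedding dimension and scaled linearly,
#' `eps_total = eps_per_dim * dim` (so 1.0 sd per dimension in a 7-D
#' embedding is a total distance of 7). Higher simplices are implicit cliques
#' and not materialized.
#'
#' @param D `dist_matrix` of pairwise distances (edge weights are these
#'   distances).
#' @param eps_per_dim Threshold per dimension (> 0), ignored if `eps_total`
#'   is given directly.
#' @param dim Embedding dimension used to scale `eps_per_dim`.
#' @param eps_total Optional absolute threshold, overriding
#'   `eps_per_dim * dim`.
#' @return Object of class `neighbor_graph`: list with `labels`, `edges`
#'   (data frame `from,to,weight`), `eps_per_dim`, `eps_total`,
#'   `n_components`.
#' @export
build_neighbor_graph <- function(D, eps_per_dim = NULL, dim = NULL,
                                 eps_total = NULL) {
  D <- .as_dist_matrix(D)
  if (anyNA(D)) stop("neighbor graph requires a complete distance matrix")
  if (is.null(eps_total)) {
    if (is.null(eps_per_dim) || is.null(dim))
      stop("supply eps_total, or eps_per_dim together with dim")
    if (eps_per_dim <= 0) stop("eps_per_dim must be positive")
    eps_total <- eps_per_dim * dim
  }
  labs <- rownames(D)
  ut <- which(upper.tri(D) & unclass(D) <= eps_total, arr.ind = TRUE)
  edges <- data.frame(from = labs[ut[, 1L]], to = labs[ut[, 2L]],
                      weight = D[ut], stringsAsFactors = FALSE)
  structure(list(labels = labs, edges = edges,
                 eps_per_dim = if (is.null(eps_per_dim)) NA_real_
                               else eps_per_dim,
                 eps_total = eps_total,
                 n_components = .n_components_edges(labs, edges)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d edges (eps_total = %.4g), %d component(s)\n",
              length(x$labels), nrow(x$edges), x$eps_total, x$n_components))
  invisible(x)
}

# Union-find component count over a labelled edge list.
.n_components_edges <- function(labels, edges) {
  parent <- seq_along(labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(match(edges$from[e], labels))
    b <- find(match(edges$to[e], labels))
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(labels), find, integer(1L))))
}

#' Smallest grid epsilon achieving full connectivity
#'
#' Incrementally increases the per-dimension threshold on a grid of step
#' `grid_step` and returns the lowest value at which all points form one
#' connected component. (Exactly, connectivity is first reached when
#' `eps_total` equals the largest MST edge weight; the grid scan mirrors the
#' filtration procedure.)
#'
#' @inheritParams build_neighbor_graph
#' @param grid_step Positive grid increment for `eps_per_dim`.
#' @return The minimal `eps_per_dim` grid value giving one component.
#' @export
min_connectivity_eps <- function(D, dim, grid_step = 0.05) {
  D <- .as_dist_matrix(D)
  if (grid_step <= 0) stop("grid_step must be positive")
  eps <- grid_step
  repeat {
    g <- build_neighbor_graph(D, eps_per_dim = eps, dim = dim)
    if (g$n_components == 1L) return(eps)
    eps <- eps + grid_step
  }
}

#' Minimum spanning tree by Prim's algorithm
#'
#' Grows the tree from the lexicographically first label, repeatedly adding
#' the smallest-weight edge joining a new node. With all-distinct weights the
#' result is the unique global MST; ties are broken deterministically by
#' lexicographic label pair.
#'
#' @param graph A `neighbor_graph`, or a complete `dist_matrix` (treated as
#'   a complete graph).
#' @return Object of class `spanning_tree`: list with `labels`, `edges`
#'   (data frame `from,to,weight`, n-1 rows), `total_weight`, `root`
#'   (`NULL` until assigned).
#' @export
prim_mst <- function(graph) {
  if (inherits(graph, "dist_matrix") || is.matrix(graph))
    graph <- build_neighbor_graph(graph, eps_total = Inf)
  labs <- graph$labels
  n <- length(labs)
  if (graph$n_components != 1L)
    stop("graph is disconnected (", graph$n_components,
         " components); increase epsilon")
  W <- matrix(Inf, n, n, dimnames = list(labs, labs))
  ei <- match(graph$edges$from, labs)
  ej <- match(graph$edges$to, labs)
  W[cbind(ei, ej)] <- W[cbind(ej, ei)] <- graph$edges$weight
  start <- order(labs)[1L]
  in_tree <- rep(FALSE, n); in_tree[start] <- TRUE
  best_w <- W[start, ]
  best_from <- rep(start, n)
  edges <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    w <- best_w[cand]
    # min weight; ties -> smaller (from, to) label pair lexicographically
    m <- min(w)
    tied <- cand[w == m]
    if (length(tied) > 1L) {
      key <- paste(pmin(labs[best_from[tied]], labs[tied]),
                   pmax(labs[best_from[tied]], labs[tied]))
      tied <- tied[order(key)]
    }
    v <- tied[1L]
    if (!is.finite(best_w[v])) stop("graph is disconnected")
    edges[[k]] <- data.frame(from = labs[best_from[v]], to = labs[v],
                             weight = best_w[v], stringsAsFactors = FALSE)
    in_tree[v] <- TRUE
    upd <- which(!in_tree & W[v, ] < best_w)
    best_w[upd] <- W[v, upd]
    best_from[upd] <- v
  }
  spanning_tree(do.call(rbind, edges), labels = labs)
}

#' Construct / validate a spanning tree
#'
#' @param edges Data frame `from,to,weight` with `n - 1` rows.
#' @param labels Node label set; defaults to the labels present in `edges`.
#' @param root Optional root label.
#' @return A `spanning_tree`.
#' @export
spanning_tree <- function(edges, labels = NULL, root = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:3] <- c("from", "to", "weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (is.null(labels)) labels <- sort(unique(c(edges$from, edges$to)))
  n <- length(labels)
  if (nrow(edges) != n - 1L)
    stop("a spanning tree over ", n, " nodes needs ", n - 1L, " edges")
  if (!all(c(edges$from, edges$to) %in% labels))
    stop("edge endpoint not in label set")
  if (.n_components_edges(labels, edges) != 1L)
    stop("edges do not form a connected tree")
  if (!is.null(root) && !root %in% labels)
    stop("root '", root, "' not in label set")
  structure(list(labels = labels, edges = edges,
                 total_weight = sum(edges$weight), root = root),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges, total weight %.6g%s\n",
              length(x$labels), nrow(x$edges), x$total_weight,
              if (is.null(x$root)) "" else paste0(", root ", x$root)))
  invisible(x)
}

# Adjacency list of a spanning tree: label -> data.frame(node, weight).
.tree_adjacency <- function(tree) {
  adj <- stats::setNames(vector("list", length(tree$labels)), tree$labels)
  for (e in seq_len(nrow(tree$edges))) {
    f <- tree$edges$from[e]; t <- tree$edges$to[e]; w <- tree$edges$weight[e]
    adj[[f]] <- rbind(adj[[f]], data.frame(node = t, weight = w))
    adj[[t]] <- rbind(adj[[t]], data.frame(node = f, weight = w))
  }
  adj
}

#' Cumulative root-to-node distances
#'
#' Sums edge weights along the unique tree path from the root to every node.
#' Sorting the result ascending gives the complexity chronology (root = the
#' least complex amino acid, glycine, by default).
#'
#' @param tree A `spanning_tree`.
#' @param root Root label (default `"G"`).
#' @return Named numeric vector of cumulative distances, in `tree$labels`
#'   order; the root maps to 0.
#' @export
root_to_node <- function(tree, root = "G") {
  if (!root %in% tree$labels) stop("unknown root '", root, "'")
  adj <- .tree_adjacency(tree)
  dist <- stats::setNames(rep(NA_real_, length(tree$labels)), tree$labels)
  dist[root] <- 0
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj[[v]]
    for (i in seq_len(NROW(nb))) {
      u <- nb$node[i]
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + nb$weight[i]
        queue <- c(queue, u)
      }
    }
  }
  dist
}

#' Chronology order from a rooted tree
#'
#' @inheritParams root_to_node
#' @return Character vector of labels sorted by ascending cumulative
#'   root-to-node distance (ties by label).
#' @export
chronology_order <- function(tree, root = "G") {
  d <- root_to_node(tree, root)
  names(sort(d))
}

#' Rank-based composite chronology
#'
#' Ranks amino acids from lowest to highest value within each metric.
#' Near-ties are grouped: on each metric's min-max-normalized scale, sorted
#' consecutive values within `tie_threshold` of one another share a rank
#' (rank = group index). Final ranks are averaged across metrics into a
#' composite score.
#'
#' @param table A complete [metrics_table()] (or numeric matrix).
#' @param tie_threshold Grouping threshold on the normalized (0-1) scale,
#'   default 0.005.
#' @return List with `ranks` (matrix, one column per metric), `composite`
#'   (named mean rank per amino acid), `order` (labels by ascending
#'   composite).
#' @export
rank_chronology <- function(table, tie_threshold = 0.005) {
  m <- unclass(as.matrix(table))
  if (anyNA(m)) stop("rank chronology requires a complete table")
  ranks <- apply(m, 2L, function(v) {
    rng <- range(v)
    vn <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
    o <- order(vn)
    grp <- integer(length(v))
    g <- 1L
    grp[o[1L]] <- g
    for (i in seq_along(o)[-1L]) {
      if (vn[o[i]] - vn[o[i - 1L]] > tie_threshold) g <- g + 1L
      grp[o[i]] <- g
    }
    grp
  })
  rownames(ranks) <- rownames(m)
  composite <- rowMeans(ranks)
  list(ranks = ranks, composite = composite,
       order = names(sort(composite)))
}

# Canonical unordered edge keys of a tree.
.edge_keys <- function(tree) {
  paste(pmin(tree$edges$from, tree$edges$to),
        pmax(tree$edges$from, tree$edges$to), sep = "|")
}

#' Compare two trees over the same label set
#'
#' Jaccard similarity = shared edges / edges in the union; adjacency
#' similarity = 1 minus the normalized Hamming distance between adjacency
#' matrices (differing unordered vertex pairs over `choose(n, 2)`).
#'
#' @param t1,t2 `spanning_tree` objects with identical label sets.
#' @return List with `jaccard` and `adjacency_similarity`.
#' @export
compare_trees <- function(t1, t2) {
  if (!setequal(t1$labels, t2$labels)) stop("label sets differ")
  e1 <- .edge_keys(t1); e2 <- .edge_keys(t2)
  shared <- length(intersect(e1, e2))
  n <- length(t1$labels)
  hamming <- (length(e1) - shared) + (length(e2) - shared)
  list(jaccard = shared / length(union(e1, e2)),
       adjacency_similarity = 1 - hamming / choose(n, 2))
}

#' Newick string of a rooted tree
#'
#' Branch lengths are the tree's edge weights; children are ordered
#' lexicographically.
#'
#' @inheritParams root_to_node
#' @return Newick string, e.g. `"(B:2)A;"`.
#' @export
as_newick <- function(tree, root = tree$root) {
  if (is.null(root)) stop("Newick export requires a root")
  if (!root %in% tree$labels) stop("unknown root '", root, "'")
  adj <- .tree_adjacency(tree)
  rec <- function(v, parent) {
    nb <- adj[[v]]
    kids <- if (NROW(nb) && !is.na(parent))
      nb[nb$node != parent, , drop = FALSE] else nb
    if (NROW(kids) == 0L) return(v)
    kids <- kids[order(kids$node), , drop = FALSE]
    parts <- vapply(seq_len(nrow(kids)), function(i)
      paste0(rec(kids$node[i], v), ":", format(kids$weight[i], digits = 15)),
      character(1L))
    paste0("(", paste(parts, collapse = ","), ")", v)
  }
  paste0(rec(root, NA_character_), ";")
}

#' Export a tree to TSV or Newick
#'
#' @param tree A `spanning_tree`.
#' @param path Output path.
#' @param format `"tsv"` (weighted edge list `from\tto\tweight`) or
#'   `"newick"` (requires a root).
#' @param root Root for Newick export (default the tree's root).
#' @export
export_tree <- function(tree, path, format = c("tsv", "newick"),
                        root = tree$root) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(tree$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    writeLines(as_newick(tree, root), path)
  }
  invisible(path)
}

#' Read a spanning tree from an edge-list TSV
#'
#' @param path TSV with columns `from`, `to`, `weight`.
#' @return A `spanning_tree`.
#' @export
read_tree_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  spanning_tree(df)
}
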