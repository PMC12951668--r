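# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# --- genetic code -----------------------------------------------------------

# Standard-code sense codons and their amino acids via Biostrings (external
# source of the code table).
oracle_sense_codons <- function() {
  gc <- Biostrings::getGeneticCode("1")
  names(gc) <- chartr("T", "U", names(gc))
  gc[gc != "*"]
}

# Brute-force enumeration of all 61 x 3 x 3 ordered substitution events:
# for every sense codon, position, and alternative base, classify the event.
# Returns per-position ordered counts of non-synonymous, non-stop events.
oracle_position_event_counts <- function() {
  sense <- oracle_sense_codons()
  gc <- Biostrings::getGeneticCode("1")
  names(gc) <- chartr("T", "U", names(gc))
  bases <- c("A", "C", "G", "U")
  counts <- c(0L, 0L, 0L)
  for (codon in names(sense)) {
    ch <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        mut <- ch
        mut[p] <- b
        mutc <- paste(mut, collapse = "")
        target <- gc[[mutc]]
        if (target != "*" && target != sense[[codon]])
          counts[p] <- counts[p] + 1L
      }
    }
  }
  counts
}

# Brute-force pairwise count matrix for one position from raw codon strings.
oracle_count_matrix <- function(position) {
  sense <- oracle_sense_codons()
  aa <- aa_symbols()
  S <- matrix(0L, 20, 20, dimnames = list(aa, aa))
  cods <- names(sense)
  for (i in seq_along(cods)) {
    for (j in seq_along(cods)) {
      if (i == j || sense[[i]] == sense[[j]]) next
      d <- which(strsplit(cods[i], "")[[1]] != strsplit(cods[j], "")[[1]])
      if (length(d) == 1 && d == position)
        S[sense[[i]], sense[[j]]] <- S[sense[[i]], sense[[j]]] + 1L
    }
  }
  S / 2L + t(S) / 2L  # ordered (c,c') and (c',c) both hit; keep one each
}

# --- graphs -----------------------------------------------------------------

# Recursive walk counter: number of walks of length 1..L starting anywhere.
oracle_walk_count <- function(A, L) {
  n <- nrow(A)
  walks_from <- function(v, len) {
    if (len == 0) return(1)
    sum(vapply(which(A[v, ] > 0), walks_from, numeric(1), len = len - 1))
  }
  total <- 0
  for (len in seq_len(L))
    for (v in seq_len(n)) total <- total + walks_from(v, len)
  total
}

# Exhaustive minimum spanning tree: try every (n-1)-subset of edges.
oracle_exhaustive_mst <- function(labels, edges) {
  n <- length(labels)
  combos <- utils::combn(nrow(edges), n - 1)
  best <- NULL
  best_w <- Inf
  for (k in seq_len(ncol(combos))) {
    sub <- edges[combos[, k], , drop = FALSE]
    if (codechron:::.n_components_edges(labels, sub) == 1L) {
      w <- sum(sub$weight)
      if (w < best_w) {
        best_w <- w
        best <- sub
      }
    }
  }
  list(edges = best, weight = best_w)
}

# Independent Kruskal implementation (sort edges, union-find).
oracle_kruskal <- function(labels, edges) {
  edges <- edges[order(edges$weight), , drop = FALSE]
  parent <- seq_along(labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- find(match(edges$from[e], labels))
    b <- find(match(edges$to[e], labels))
    if (a != b) {
      parent[a] <- b
      keep[e] <- TRUE
    }
  }
  edges[keep, , drop = FALSE]
}

# Random connected weighted graph: random tree plus extra edges, all
# weights distinct.
random_connected_graph <- function(n, extra = n) {
  tree <- gen_random_tree(n, labels = LETTERS[seq_len(n)])
  all_pairs <- t(utils::combn(LETTERS[seq_len(n)], 2))
  key <- paste(all_pairs[, 1], all_pairs[, 2])
  tree_key <- paste(pmin(tree$edges$from, tree$edges$to),
                    pmax(tree$edges$from, tree$edges$to))
  avail <- which(!key %in% tree_key)
  add <- sample(avail, min(extra, length(avail)))
  edges <- rbind(tree$edges[, c("from", "to")],
                 data.frame(from = all_pairs[add, 1],
                            to = all_pairs[add, 2]))
  edges$weight <- sample(seq_len(nrow(edges) * 10), nrow(edges)) / 10
  list(labels = LETTERS[seq_len(n)], edges = edges)
}

neighbor_graph_from_edges <- function(labels, edges) {
  structure(list(labels = labels, edges = edges,
                 eps_per_dim = NA_real_, eps_total = Inf,
                 n_components = codechron:::.n_components_edges(labels,
                                                                edges)),
            class = "neighbor_graph")
}

edge_key_set <- function(edges) {
  sort(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
             sep = "|"))
}

# --- fixtures ---------------------------------------------------------------

toy_metrics_path <- function() {
  system.file("extdata", "toy_metrics6.csv", package = "codechron")
}

# Random points whose distance matrix is exactly Euclidean of known rank.
random_euclidean_D <- function(n, rank, labels = NULL) {
  pts <- matrix(rnorm(n * rank), n, rank)
  rownames(pts) <- if (is.null(labels)) as.character(seq_len(n)) else labels
  codechron:::.as_dist_matrix(as.matrix(dist(pts)))
}
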