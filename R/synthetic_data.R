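# Seed-deterministic generators emulating the statistical structure the
# analysis assumes: low-rank metric tables with block correlation, usage
# vectors linear in a chronology score, alkane path graphs, and uniform
# random labelled trees (Pruefer construction).

#' Generate a synthetic complexity metrics table
#'
#' Draws `values = Z %*% t(F) + noise` with latent scores `Z` (entities x
#' `latent_rank`) standard normal and metric loadings `F` built from two
#' block directions: graph-framework metrics load on one common direction,
#' information-framework metrics on a second direction correlated with the
#' first at `between_cor`; `within_cor` controls how tightly metrics within
#' a block share their direction. With `noise_sd = 0` the table has exact
#' rank `latent_rank`, so MDS recovers the latent dimension exactly.
#'
#' @param n_entities Number of rows (20 gives a [metrics_table()] over the
#'   amino acids; other sizes return a plain labelled matrix).
#' @param n_metrics Total metric columns (default 16).
#' @param n_graph How many columns are tagged `graph` (default 7; the rest
#'   are `information`).
#' @param latent_rank Latent dimension (default 2).
#' @param noise_sd Standard deviation of additive Gaussian noise (default
#'   0.05).
#' @param within_cor,between_cor Within-block direction coherence and
#'   between-block direction correlation, both in `[0, 1]`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A [metrics_table()] (20 entities) or labelled numeric matrix,
#'   with a `framework` attribute and a `seed` attribute.
#' @export
gen_metric_table <- function(n_entities = 20, n_metrics = 16, n_graph = 7,
                             latent_rank = 2, noise_sd = 0.05,
                             within_cor = 0.8, between_cor = 0.2,
                             seed = NULL) {
  if (latent_rank > min(n_entities, n_metrics))
    stop("latent_rank must be <= min(n_entities, n_metrics)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_graph > n_metrics) stop("n_graph must be <= n_metrics")
  if (!is.null(seed)) set.seed(seed)
  r <- latent_rank
  unit <- function(v) v / sqrt(sum(v^2))
  g_dir <- unit(stats::rnorm(r))
  orth <- stats::rnorm(r)
  orth <- orth - sum(orth * g_dir) * g_dir
  orth <- if (sum(orth^2) > 0) unit(orth) else g_dir
  i_dir <- if (r == 1L) g_dir
           else unit(between_cor * g_dir + sqrt(1 - between_cor^2) * orth)
  load_one <- function(dir) {
    raw <- sqrt(within_cor) * dir +
      sqrt(1 - within_cor) * stats::rnorm(r)
    raw * stats::runif(1L, 0.8, 1.2)   # scale variety across metrics
  }
  F_load <- rbind(
    t(vapply(seq_len(n_graph), function(i) load_one(g_dir), numeric(r))),
    t(vapply(seq_len(n_metrics - n_graph), function(i) load_one(i_dir),
             numeric(r))))
  Z <- matrix(stats::rnorm(n_entities * r), n_entities, r)
  vals <- Z %*% t(F_load) +
    matrix(stats::rnorm(n_entities * n_metrics, sd = noise_sd),
           n_entities, n_metrics)
  labs <- if (n_entities == 20L) aa_symbols()
          else sprintf("E%02d", seq_len(n_entities))
  rownames(vals) <- labs
  colnames(vals) <- c(sprintf("g%02d", seq_len(n_graph)),
                      sprintf("i%02d", seq_len(n_metrics - n_graph)))
  fw <- stats::setNames(rep(c("graph", "information"),
                            c(n_graph, n_metrics - n_graph)),
                        colnames(vals))
  out <- if (n_entities == 20L) metrics_table(vals, fw)
         else structure(vals, framework = fw)
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic usage table linear in a chronology score
#'
#' `usage = intercept + slope * score + N(0, noise_sd^2)`, truncated at 0.
#' Defaults emulate the magnitude of the decreasing usage-versus-complexity
#' relation on a root-to-node score scale of roughly 0-20 with usages
#' summing to ~1.
#'
#' @param scores Named numeric chronology scores for the 20 amino acids.
#' @param slope,intercept Linear coefficients.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame `label, usage, stderr` (stderr = `noise_sd`).
#' @export
gen_usage <- function(scores, slope = -0.004, intercept = 0.08,
                      noise_sd = 0.012, seed = NULL) {
  if (length(scores) != 20L || is.null(names(scores)))
    stop("scores must be a named vector over the 20 amino acids")
  if (!is.null(seed)) set.seed(seed)
  usage <- intercept + slope * scores + stats::rnorm(20L, sd = noise_sd)
  usage <- pmax(usage, 0)
  data.frame(label = names(scores), usage = unname(usage),
             stderr = noise_sd, stringsAsFactors = FALSE)
}

#' Hydrogen-suppressed n-alkane backbone graph
#'
#' A path graph of `n` sp3 carbons with no chiral centers; the walk-count
#' anchor series (TWC 2 for n = 2 up to 6500 for n = 10).
#'
#' @param n_vertices Number of carbons, >= 2.
#' @return A [molecular_graph()].
#' @export
gen_path_alkane <- function(n_vertices) {
  if (n_vertices < 2L) stop("an alkane backbone needs >= 2 carbons")
  molecular_graph(rep("C", n_vertices),
                  cbind(seq_len(n_vertices - 1L), 2:n_vertices),
                  sp3 = rep(TRUE, n_vertices))
}

#' Decode a Pruefer sequence into tree edges
#'
#' @param seq Integer vector in `1..n` of length `n - 2` (empty for
#'   `n = 2`).
#' @param n Number of nodes.
#' @return `(n-1) x 2` integer edge matrix.
#' @export
prufer_to_edges <- function(seq, n) {
  if (length(seq) != n - 2L) stop("Pruefer sequence must have length n - 2")
  degree <- rep(1L, n) + tabulate(seq, nbins = n)
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, seq[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

#' Encode a labelled tree as its Pruefer sequence
#'
#' Inverse of [prufer_to_edges()] (round-trips exactly).
#'
#' @param edges `(n-1) x 2` integer edge matrix over nodes `1..n`.
#' @param n Number of nodes.
#' @return Integer Pruefer sequence of length `n - 2`.
#' @export
edges_to_prufer <- function(edges, n) {
  adj <- lapply(seq_len(n), function(i) integer(0L))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  degree <- lengths(adj)
  out <- integer(max(n - 2L, 0L))
  removed <- rep(FALSE, n)
  for (i in seq_len(n - 2L)) {
    leaf <- which(degree == 1L & !removed)[1L]
    nb <- adj[[leaf]][!removed[adj[[leaf]]]][1L]
    out[i] <- nb
    removed[leaf] <- TRUE
    degree[leaf] <- 0L
    degree[nb] <- degree[nb] - 1L
  }
  out
}

#' Generate a uniform random labelled tree
#'
#' Draws a uniform random Pruefer sequence and decodes it, giving a
#' uniformly distributed labelled tree with unit edge weights.
#'
#' @param n_nodes Number of nodes (>= 2); 20 labels as amino acids,
#'   otherwise `N01..`.
#' @param seed Integer seed.
#' @param labels Optional explicit node labels.
#' @return A `spanning_tree` with unit weights.
#' @export
gen_random_tree <- function(n_nodes = 20, seed = NULL, labels = NULL) {
  if (n_nodes < 2L) stop("a tree needs >= 2 nodes")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels))
    labels <- if (n_nodes == 20L) aa_symbols()
              else sprintf("N%02d", seq_len(n_nodes))
  seq <- if (n_nodes > 2L) sample.int(n_nodes, n_nodes - 2L, replace = TRUE)
         else integer(0L)
  edges <- prufer_to_edges(seq, n_nodes)
  spanning_tree(data.frame(from = labels[edges[, 1L]],
                           to = labels[edges[, 2L]],
                           weight = 1, stringsAsFactors = FALSE),
                labels = labels)
}
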