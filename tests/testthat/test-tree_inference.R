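# Epsilon graph, Prim MST vs independent algorithms, chronology, ranks,
# tree comparison and serialization.

test_that("neighbor graph thresholds edges at eps_total = eps_per_dim * dim", {
  m <- rbind(a = 0, b = 1, c = 5)
  colnames(m) <- "x"
  D <- distance_matrix(m)
  empty <- build_neighbor_graph(D, eps_total = 0.5)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(empty$n_components, 3L)
  full <- build_neighbor_graph(D, eps_total = 10)
  expect_equal(nrow(full$edges), 3L)
  expect_equal(full$n_components, 1L)
  # linear scaling: eps_per_dim 1 in 7 dims = total 7
  g7 <- build_neighbor_graph(D, eps_per_dim = 1, dim = 7)
  expect_equal(g7$eps_total, 7)
  # two clusters separated by gap 4: just below the gap -> 2 components
  mid <- build_neighbor_graph(D, eps_total = 3.9)
  expect_equal(mid$n_components, 2L)
})

test_that("min_connectivity_eps scans the grid to the bridging gap", {
  m <- rbind(a = 0, b = 1, c = 5)
  colnames(m) <- "x"
  D <- distance_matrix(m)
  # connects when eps_total reaches the largest gap, 4; dim = 1
  expect_equal(min_connectivity_eps(D, dim = 1, grid_step = 0.5), 4)
  expect_equal(min_connectivity_eps(D, dim = 1, grid_step = 0.3), 4.2)
  # refinement property: halving the grid never increases the report
  set.seed(14)
  D2 <- random_euclidean_D(8, 2)
  e1 <- min_connectivity_eps(D2, dim = 2, grid_step = 0.1)
  e2 <- min_connectivity_eps(D2, dim = 2, grid_step = 0.05)
  expect_lte(e2, e1)
})

test_that("min-connectivity epsilon equals the largest MST edge (equivalence)", {
  set.seed(15)
  for (rep in 1:5) {
    D <- random_euclidean_D(sample(6:12, 1), 3)
    crit <- max(prim_mst(D)$edges$weight)
    fine <- 1e-4
    eps <- min_connectivity_eps(D, dim = 1, grid_step = fine)
    expect_lt(abs(eps - crit), fine + 1e-12)
  }
})

test_that("Prim equals Kruskal, igraph, and exhaustive enumeration", {
  set.seed(16)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    g <- random_connected_graph(n, extra = sample(1:4, 1))
    ng <- neighbor_graph_from_edges(g$labels, g$edges)
    mst <- prim_mst(ng)
    expect_equal(nrow(mst$edges), n - 1L)
    # independent Kruskal
    kr <- oracle_kruskal(g$labels, g$edges)
    expect_equal(edge_key_set(mst$edges), edge_key_set(kr))
    # igraph
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE)
    im <- igraph::mst(ig, weights = igraph::E(ig)$weight)
    ie <- igraph::as_data_frame(im)
    expect_equal(edge_key_set(mst$edges),
                 edge_key_set(data.frame(from = ie$from, to = ie$to)))
    # exhaustive (small instances)
    if (n <= 6) {
      ex <- oracle_exhaustive_mst(g$labels, g$edges)
      expect_equal(mst$total_weight, ex$weight)
      expect_equal(edge_key_set(mst$edges), edge_key_set(ex$edges))
    }
  }
})

test_that("Prim is deterministic under ties and errors on disconnection", {
  edges <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                      weight = c(1, 1, 1))
  ng <- neighbor_graph_from_edges(c("a", "b", "c"), edges)
  t1 <- prim_mst(ng)
  t2 <- prim_mst(ng)
  expect_identical(t1$edges, t2$edges)
  disc <- neighbor_graph_from_edges(c("a", "b", "c"),
                                    edges[1, , drop = FALSE])
  expect_error(prim_mst(disc), "disconnected")
  # triangle 1/2/3 keeps the two lightest edges
  tri <- neighbor_graph_from_edges(
    c("a", "b", "c"),
    data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
               weight = c(1, 2, 3)))
  expect_equal(prim_mst(tri)$total_weight, 3)
})

test_that("MST topology survives strictly monotone weight transforms", {
  set.seed(17)
  g <- random_connected_graph(7, extra = 5)
  ng <- neighbor_graph_from_edges(g$labels, g$edges)
  base <- prim_mst(ng)
  g2 <- g
  g2$edges$weight <- exp(g$edges$weight)  # strictly monotone
  warped <- prim_mst(neighbor_graph_from_edges(g2$labels, g2$edges))
  expect_equal(edge_key_set(base$edges), edge_key_set(warped$edges))
})

test_that("root_to_node accumulates path weights; order is scale-invariant", {
  chain <- spanning_tree(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    weight = c(2, 3)))
  d <- root_to_node(chain, "A")
  expect_equal(d, c(A = 0, B = 2, C = 5))
  expect_equal(chronology_order(chain, "A"), c("A", "B", "C"))
  expect_error(root_to_node(chain, "Z"), "unknown root")
  set.seed(18)
  D <- random_euclidean_D(10, 3, labels = LETTERS[1:10])
  t1 <- prim_mst(D)
  o1 <- chronology_order(t1, "A")
  t2 <- prim_mst(codechron:::.as_dist_matrix(unclass(D) * 3.7))
  expect_equal(chronology_order(t2, "A"), o1)
})

test_that("rank chronology groups near-ties on the normalized scale", {
  v <- seq(0, 1, length.out = 20)
  m <- cbind(m1 = v)
  rownames(m) <- aa_symbols()
  rc <- rank_chronology(m)
  expect_equal(unname(rc$ranks[, 1]), 1:20)
  # two values 0.004 apart on the normalized scale share a rank
  v2 <- c(0, 0.004, seq(0.2, 1, length.out = 18))
  m2 <- cbind(m1 = v2)
  rownames(m2) <- aa_symbols()
  rc2 <- rank_chronology(m2)
  expect_equal(rc2$ranks[1, 1], rc2$ranks[2, 1])
  expect_equal(max(rc2$ranks[, 1]), 19)
  # identical columns: composite equals a single column's ranks
  m3 <- cbind(m1 = v, m2 = v, m3 = v)
  rownames(m3) <- aa_symbols()
  rc3 <- rank_chronology(m3)
  expect_equal(unname(rc3$composite), 1:20)
})

test_that("tree comparison: Jaccard and adjacency similarity", {
  set.seed(19)
  t1 <- gen_random_tree(20, seed = 1)
  expect_equal(compare_trees(t1, t1),
               list(jaccard = 1, adjacency_similarity = 1))
  t2 <- gen_random_tree(20, seed = 2)
  cmp <- compare_trees(t1, t2)
  shared <- length(intersect(edge_key_set(t1$edges), edge_key_set(t2$edges)))
  expect_equal(cmp$jaccard, shared / (38 - shared))
  expect_equal(cmp$adjacency_similarity,
               1 - 2 * (19 - shared) / choose(20, 2))
  t3 <- gen_random_tree(5, seed = 3)
  expect_error(compare_trees(t1, t3), "label sets differ")
})

test_that("tree serialization round-trips; Newick parses with ape", {
  chain <- spanning_tree(data.frame(from = "A", to = "B", weight = 2))
  expect_equal(as_newick(chain, "A"), "(B:2)A;")
  t1 <- gen_random_tree(20, seed = 20)
  t1$edges$weight <- runif(19, 1, 3)
  t1 <- spanning_tree(t1$edges)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  export_tree(t1, tmp, "tsv")
  expect_equal(length(readLines(tmp)), 20L)  # header + 19 edges
  back <- read_tree_tsv(tmp)
  expect_equal(edge_key_set(back$edges), edge_key_set(t1$edges))
  expect_equal(back$total_weight, t1$total_weight)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  export_tree(t1, nwk, "newick", root = "G")
  ph <- ape::read.tree(nwk)
  # independent parser: total branch length and node count are conserved
  expect_equal(sum(ph$edge.length), t1$total_weight, tolerance = 1e-9)
  expect_equal(length(ph$tip.label) + ph$Nnode, 20L)
})
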