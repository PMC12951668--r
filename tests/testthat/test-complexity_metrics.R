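# Topological indices, composites, and the metrics-table reader.

test_that("molecular_graph validates its inputs", {
  expect_error(molecular_graph("C", cbind(1, 1)), "self-loop")
  expect_error(molecular_graph(c("C", "C"), cbind(1, 3)), "out of range")
  expect_error(molecular_graph(c("C", "C", "C"), cbind(1, 2)), "connected")
  expect_error(molecular_graph(c("C", "C"), rbind(c(1, 2), c(2, 1))),
               "duplicate")
  g <- molecular_graph(c("C", "N"), cbind(1, 2))
  expect_s3_class(g, "molecular_graph")
})

test_that("walk counts hit the alkane anchors and a brute-force enumerator", {
  expect_equal(total_walk_count(gen_path_alkane(2)), 2)
  expect_equal(total_walk_count(gen_path_alkane(3)), 10)
  expect_equal(total_walk_count(gen_path_alkane(10)), 6500)
  expect_error(total_walk_count(molecular_graph("C", matrix(0, 0, 2))),
               "single-atom")
  # property: matches recursive enumeration on random small graphs
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(3:7, 1)
    g <- random_connected_graph(n, extra = sample(0:2, 1))
    mg <- molecular_graph(rep("C", n),
                          cbind(match(g$edges$from, g$labels),
                                match(g$edges$to, g$labels)))
    A <- adjacency_matrix(mg)
    expect_equal(total_walk_count(mg), oracle_walk_count(A, n - 1))
  }
  # monotone in path length
  twc <- vapply(2:9, function(n) total_walk_count(gen_path_alkane(n)),
                numeric(1))
  expect_true(all(diff(twc) > 0))
})

test_that("logWCX is base-10 log of the walk count", {
  expect_equal(log_wcx(gen_path_alkane(2)), log10(2))
  expect_equal(log_wcx(gen_path_alkane(3)), 1)
  expect_equal(log_wcx(gen_path_alkane(10)), log10(6500))
})

test_that("Zagreb, kappa and Balaban match closed forms on paths/stars/cycles", {
  path3 <- gen_path_alkane(3)
  star4 <- molecular_graph(rep("C", 4), cbind(1, 2:4))
  edge <- gen_path_alkane(2)
  cycle3 <- molecular_graph(rep("C", 3), rbind(c(1, 2), c(2, 3), c(1, 3)))
  cycle6 <- molecular_graph(rep("C", 6),
                            cbind(1:6, c(2:6, 1)))

  expect_equal(zagreb_indices(path3), c(M1 = 6, M2 = 4))
  expect_equal(zagreb_indices(star4), c(M1 = 12, M2 = 9))
  expect_equal(zagreb_indices(edge), c(M1 = 2, M2 = 1))
  expect_equal(zagreb_indices(cycle6), c(M1 = 24, M2 = 24))

  k3 <- kappa_indices(path3)
  expect_equal(unname(k3[c("K1", "K2")]), c(3, 2))
  expect_true(is.na(k3["K3"]))
  # 4-path: A=4, P1=3, P2=2, P3=1
  k4 <- kappa_indices(gen_path_alkane(4))
  expect_equal(unname(k4), c(4 * 9 / 9, 3 * 4 / 4, 1 * 4 / 1))
  # 6-cycle: P1=6, P2=6, P3=6; A even
  k6 <- kappa_indices(cycle6)
  expect_equal(unname(k6), c(6 * 25 / 36, 5 * 16 / 36, 3 * 16 / 36))

  expect_equal(balaban_j(edge), 1)
  expect_equal(balaban_j(path3), 2 * 2 / sqrt(6))
  expect_equal(balaban_j(cycle3), 2.25)
  # 6-cycle: m=6, mu=1, s_i=9 -> J = 3 * 6/9 = 2
  expect_equal(balaban_j(cycle6), 2)
})

test_that("fraction indices read annotations over the carbon denominator", {
  gly <- molecular_graph(c("N", "C", "C", "O", "O"),
                         rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)),
                         sp3 = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  fr <- fraction_indices(gly)
  expect_equal(unname(fr["FCC"]), 0)
  expect_equal(unname(fr["FSP3"]), 1 / 2)
  alk <- gen_path_alkane(5)
  expect_equal(unname(fraction_indices(alk)["FSP3"]), 1)
  g <- molecular_graph(rep("C", 3), cbind(1:2, 2:3),
                       chiral = c(TRUE, FALSE, FALSE))
  expect_equal(unname(fraction_indices(g)["FCC"]), 1 / 3)
  expect_error(fraction_indices(molecular_graph("O", matrix(0, 0, 2))),
               "carbon")
})

test_that("euclidean_combine is a norm and propagates missing values", {
  expect_equal(euclidean_combine(c(3, 4)), 5)
  expect_equal(euclidean_combine(c(0, 0, 0)), 0)
  expect_equal(euclidean_combine(c(1, 2, 2)), 3)
  expect_true(is.na(euclidean_combine(c(1, NA))))
  # permutation invariance and absolute homogeneity
  set.seed(4)
  for (rep in 1:5) {
    v <- rnorm(4)
    lam <- rnorm(1)
    expect_equal(euclidean_combine(sample(v)), euclidean_combine(v))
    expect_equal(euclidean_combine(lam * v),
                 abs(lam) * euclidean_combine(v))
  }
})

test_that("compute_graph_metrics composes the index panel; JSON reader works", {
  dec <- read_molecular_graph(system.file("extdata", "decane.json",
                                          package = "codechron"))
  m <- compute_graph_metrics(dec)
  expect_equal(unname(m["logWCX"]), log10(6500))
  expect_equal(unname(m["FSP3"]), 1)
  expect_equal(unname(m["NSMM"]),
               euclidean_combine(zagreb_indices(dec)))
})

test_that("metrics table loader validates, tags frameworks, keeps missing", {
  tb <- load_metrics_table(toy_metrics_path(), require_full = FALSE)
  expect_s3_class(tb, "metrics_table")
  expect_equal(dim(tb), c(6L, 2L))
  fw <- attr(tb, "framework")
  expect_equal(unname(fw[c("m1", "m2")]), c("graph", "information"))
  # full-set requirement
  expect_error(load_metrics_table(toy_metrics_path()), "missing amino acid")

  # 20-row synthetic table round-trips through write/load
  full <- gen_metric_table(seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(full, tmp)
  back <- load_metrics_table(tmp)
  expect_equal(unclass(back), unclass(full), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "framework"), attr(full, "framework"))

  # a missing cell is preserved, not dropped
  full2 <- unclass(full)
  full2["A", 1] <- NA
  write_metrics_table(metrics_table(full2, attr(full, "framework")), tmp)
  back2 <- load_metrics_table(tmp)
  expect_equal(sum(is.na(back2)), 1L)

  # non-numeric cell named with context
  txt <- readLines(tmp)
  txt[3] <- sub("^A,[^,]*", "A,oops", txt[3])
  writeLines(txt, tmp)
  expect_error(load_metrics_table(tmp), "row 'A'")
})
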