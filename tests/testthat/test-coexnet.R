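test_that("pearson_cc matches the product-moment formula and marks flat profiles undefined", {
  expect_equal(pearson_cc(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  expect_equal(pearson_cc(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1.0)
  # frozen from Table 1: ZmTIP1;2 vs ZmNIP1;1, verified against the raw
  # product-moment formula in extended precision
  cc <- pearson_cc(c(124.288, 11.90748, 13.80556, 12.93096),
                   c(284.4251, 55.78293, 1.32962, 0.604141))
  expect_equal(cc, 0.97908614305118, tolerance = 1e-12)
  expect_gt(cc, 0.95)
  expect_true(is.na(pearson_cc(c(5, 5, 5, 5), c(1, 2, 3, 4))))
  expect_error(pearson_cc(1:3, 1:4), "dimension error")
  expect_error(pearson_cc(1, 2), "dimension error")
})

test_that("neighbour ranks sort by descending correlation with id tie-break", {
  # toy: cc(A,B) = 0.9, cc(A,C) = 0.5 by construction
  em <- expression_matrix(rbind(c(1, 2, 3, 4),
                                c(1.2, 1.8, 3.4, 3.6),
                                c(2, 1, 4, 3)),
                          gene_ids = c("A", "B", "C"))
  rk <- rank_neighbors(correlation_matrix(em))
  expect_equal(rk["A", "B"], 1L)
  expect_equal(rk["A", "C"], 2L)
  expect_true(is.na(rk["A", "A"]))
  # exact correlation ties order by ascending gene_id
  em2 <- expression_matrix(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(3, 6, 9, 12)),
                          gene_ids = c("Z", "B", "A"))
  rk2 <- rank_neighbors(correlation_matrix(em2))
  expect_equal(rk2["Z", "A"], 1L)
  expect_equal(rk2["Z", "B"], 2L)
  # a gene undefined against everything has an empty list
  em3 <- expression_matrix(rbind(c(1, 2, 3, 4), c(5, 5, 5, 5)),
                           gene_ids = c("A", "flat"))
  rk3 <- rank_neighbors(correlation_matrix(em3))
  expect_true(all(is.na(rk3["flat", ])))
  expect_true(all(is.na(rk3[, "flat"])))
})

test_that("build_network applies the correlation floor and rank cap exactly", {
  # two identical pairs, anti-correlated across pairs -> exactly the 2 edges
  em <- expression_matrix(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8),
                                c(4, 3, 2, 1), c(8, 6, 4, 2)),
                          gene_ids = c("A", "B", "C", "D"))
  net <- build_network(em, network_params(min_cc = 0.95, max_rank = 50))
  expect_equal(edge_keys(net), c("A|B", "C|D"))
  # max_rank = 0 makes the rank condition unsatisfiable
  expect_equal(nrow(build_network(em, network_params(max_rank = 0))$edges), 0L)
  # strict inequality: a pair at exactly min_cc is not an edge
  net_eq <- build_network(em, network_params(min_cc = 1, max_rank = 50))
  expect_equal(nrow(net_eq$edges), 0L)
  # the published aquaporin network contains the ZmTIP1;2 - ZmNIP1;1 edge
  fix <- build_network(collapse_duplicates(table1_matrix())$matrix)
  expect_true("GRMZM2G041980|GRMZM2G168439" %in% edge_keys(fix))
  # duplicated ids are refused with direction to collapse_duplicates
  expect_error(build_network(table1_matrix()), "collapse_duplicates")
})

test_that("build_network agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    em <- random_small_matrix(n)
    min_cc <- sample(c(0.3, 0.6, 0.9, 0.95, 0.99), 1)
    max_rank <- sample(0:5, 1)
    mode <- sample(c("either_direction", "both_directions"), 1)
    net <- build_network(em, network_params(min_cc, max_rank, mode))
    expect_equal(edge_keys(net),
                 oracle_edges(em$values, em$gene_ids, min_cc, max_rank, mode),
                 info = sprintf("rep %d: n=%d min_cc=%.2f max_rank=%d %s",
                                rep, n, min_cc, max_rank, mode))
  }
})

test_that("the network is invariant to positive scaling/shifts and monotone in both thresholds", {
  set.seed(202)
  for (rep in 1:20) {
    em <- random_generic_matrix(sample(4:10, 1))
    p <- network_params(min_cc = 0.6, max_rank = 3)
    base <- edge_keys(build_network(em, p))
    # positive scale + shift per gene leaves Pearson, hence the network, unchanged
    scaled <- em
    scaled$values <- em$values * runif(nrow(em$values), 0.5, 20) +
      runif(nrow(em$values), 0, 100)
    expect_equal(edge_keys(build_network(scaled, p)), base)
    # raising min_cc or lowering max_rank can only remove edges
    expect_true(all(edge_keys(build_network(em, network_params(0.8, 3))) %in% base))
    expect_true(all(edge_keys(build_network(em, network_params(0.6, 2))) %in% base))
  }
  # relabeling genes yields an isomorphic network
  set.seed(303)
  em <- random_small_matrix(8)
  relab <- setNames(sprintf("H%02d", sample(8)), em$gene_ids)
  em2 <- em; em2$gene_ids <- unname(relab[em$gene_ids])
  net1 <- build_network(em, network_params(0.6, 3))
  net2 <- build_network(em2, network_params(0.6, 3))
  mapped <- sort(vapply(strsplit(edge_keys(net1), "|", fixed = TRUE),
                        function(e) paste(sort(relab[e]), collapse = "|"),
                        character(1)))
  expect_equal(edge_keys(net2), mapped)
})

test_that("graph statistics report the standard unweighted topology", {
  mk_net <- function(ids, edges_df) {
    em_dummy <- network_params()
    structure(list(nodes = ids, edges = edges_df, params = em_dummy),
              class = "CoexpressionNetwork")
  }
  e0 <- data.frame(gene_a = character(), gene_b = character(), cc = numeric(),
                   rank_ab = integer(), rank_ba = integer())
  s0 <- graph_stats(mk_net(character(), e0))
  expect_equal(s0$n_nodes, 0)
  expect_equal(s0$n_edges, 0)
  expect_equal(s0$clustering_coefficient, 0)
  expect_equal(s0$n_components, 0)
  tri <- mk_net(c("A", "B", "C"),
                data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                           cc = 1, rank_ab = 1L, rank_ba = 1L))
  st <- graph_stats(tri)
  expect_equal(st$clustering_coefficient, 1.0)
  expect_equal(st$components$diameter, 1)
  path3 <- mk_net(c("A", "B", "C"),
                  data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                             cc = 1, rank_ab = 1L, rank_ba = 1L))
  sp <- graph_stats(path3)
  expect_equal(sp$clustering_coefficient, 0)
  expect_equal(sp$components$diameter, 2)
  expect_equal(sp$components$mean_path_length, 4 / 3)
})

test_that("network exports write SIF, GraphML and an edge table", {
  em <- collapse_duplicates(table1_matrix())$matrix
  net <- build_network(em)
  prefix <- file.path(withr::local_tempdir(), "net")
  files <- write_network(net, prefix)
  sif <- readLines(paste0(prefix, ".sif"))
  expect_length(sif, nrow(net$edges) + length(graph_stats(net)$singletons))
  expect_match(sif[1], "^\\S+\t[01]\\.\\d{4}\t\\S+$")
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  tab <- read.delim(paste0(prefix, "_edges.tsv"))
  expect_equal(nrow(tab), nrow(net$edges))
})
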