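test_that("associations mirror the network edge criteria across the two sets", {
  em <- expression_matrix(rbind(c(1, 2, 3, 4),          # Q1
                                c(4, 3, 2, 1),          # Q2
                                c(2, 4, 6, 8),          # T1: scaled copy of Q1
                                c(3, 1, 4, 1)),         # T2: unrelated to both
                          gene_ids = c("Q1", "Q2", "T1", "T2"))
  tab <- associate(em, c("Q1", "Q2"), c("T1", "T2"))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$query_id, "Q1")
  expect_equal(tab$target_id, "T1")
  expect_equal(tab$cc, 1.0)
  expect_equal(attr(tab, "n_evaluated"), 4L)
  # a target anti-correlated with every query never passes at min_cc = 0.95
  anti <- expression_matrix(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)),
                            gene_ids = c("Q", "T"))
  expect_equal(nrow(associate(anti, "Q", "T")), 0L)
  expect_error(associate(em, c("Q1", "T1"), c("T1", "T2")), "overlap")
  expect_error(associate(em, "Q1", "ghost"), "lookup error")
})

test_that("a passing pair is exactly an edge of build_network on the same matrix", {
  set.seed(404)
  for (rep in 1:15) {
    em <- random_small_matrix(sample(6:12, 1))
    ids <- em$gene_ids
    q <- ids[seq_len(3)]
    t <- ids[-seq_len(3)]
    p <- network_params(min_cc = 0.6, max_rank = 3)
    tab <- associate(em, q, t, p)
    net_keys <- edge_keys(build_network(em, p))
    assoc_keys <- if (nrow(tab)) sort(apply(cbind(tab$query_id, tab$target_id), 1,
                                            function(x) paste(sort(x), collapse = "|")))
                  else character()
    cross <- Filter(function(k) {
      g <- strsplit(k, "|", fixed = TRUE)[[1]]
      (g[1] %in% q) != (g[2] %in% q)
    }, net_keys)
    expect_equal(assoc_keys, sort(cross))
  }
})

test_that("ranks in associations come from the full matrix, not the pair", {
  # adding genes uncorrelated with a passing pair can break it only via ranks
  base <- expression_matrix(rbind(c(1, 2, 3, 4), c(2, 4.1, 5.9, 8)),
                            gene_ids = c("Q", "T"))
  p_tight <- network_params(min_cc = 0.9, max_rank = 1)
  expect_equal(nrow(associate(base, "Q", "T", p_tight)), 1L)
  # insert a gene even closer to Q: T drops to rank 2 in Q's list and (with
  # rank 2 back) the pair fails under both_directions at max_rank 1
  em2 <- expression_matrix(rbind(base$values, c(2, 4, 6, 8), c(1.1, 2, 3.1, 4)),
                           gene_ids = c("Q", "T", "QQ", "QQQ"))
  p_both <- network_params(min_cc = 0.9, max_rank = 1, rank_mode = "both_directions")
  tab2 <- associate(em2, c("Q"), c("T"), p_both)
  expect_equal(nrow(tab2), 0L)
})

test_that("shared-target report groups transporters hit by several aquaporins", {
  expect_equal(nrow(shared_target_report(
    associate(expression_matrix(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)),
                                gene_ids = c("Q", "T")), "Q", "T"))), 0L)
  sim <- simulate_expression(synthetic_spec(noise_sd = 0, module_sizes = c(3, 3),
                                            n_transporters_per_prototype = 2,
                                            n_background = 0))
  tr <- sim$truth
  tab <- associate(sim$matrix, tr$gene_id[tr$role == "module"],
                   tr$gene_id[tr$role == "transporter"])
  rep <- shared_target_report(tab)
  expect_equal(nrow(rep), 4L)              # every transporter shared
  expect_true(all(rep$n_queries == 3L))    # by its full prototype block
  expect_true(all(rep$n_queries[1] >= rep$n_queries))  # descending order
  p1 <- sort(tr$gene_id[tr$role == "module" & tr$prototype == 1])
  expect_equal(rep$queries[rep$target_id == "TRANS1_G001"],
               paste(p1, collapse = ","))
})

test_that("zero-noise planted transporter ties are recovered exactly", {
  sim <- simulate_expression(synthetic_spec(noise_sd = 0))
  tr <- sim$truth
  queries <- tr$gene_id[tr$role == "module"]
  targets <- tr$gene_id[tr$role == "transporter"]
  tab <- associate(sim$matrix, queries, targets)
  for (p in 1:2) {
    tp <- tr$gene_id[tr$role == "transporter" & tr$prototype == p]
    qp <- tr$gene_id[tr$role == "module" & tr$prototype == p]
    for (t in tp)
      expect_setequal(tab$query_id[tab$target_id == t], qp)
  }
  # and no cross-prototype association exists
  proto_of <- setNames(tr$prototype, tr$gene_id)
  expect_true(all(proto_of[tab$query_id] == proto_of[tab$target_id]))
})
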