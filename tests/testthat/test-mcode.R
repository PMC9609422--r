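clique_net <- function(ids, extra = NULL, confidence = 1) {
  pairs <- t(utils::combn(ids, 2))
  ed <- data.frame(a = pairs[, 1], b = pairs[, 2], confidence = confidence,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) ed <- rbind(ed, extra)
  ppi_network(ed)
}

test_that("k-core extraction prunes to the definitional fixpoint", {
  tri_pendant <- net_from_pairs("A","B", "B","C", "A","C", "C","D")
  core2 <- k_core_subgraph(tri_pendant, 2)
  expect_setequal(network_nodes(core2), c("A", "B", "C"))
  # trees have no 2-core
  tree <- net_from_pairs("A","B", "B","C", "B","D", "D","E")
  expect_equal(network_summary(k_core_subgraph(tree, 2))$n_nodes, 0L)
})

test_that("k-core matches the naive iterative-deletion oracle on random graphs", {
  for (seed in 1:8) {
    net <- random_gnp_net(60, 0.07, seed = 400 + seed)
    for (k in 2:4) {
      expect_equal(network_nodes(k_core_subgraph(net, k)),
                   oracle_kcore_nodes(net, k))
    }
  }
})

test_that("vertex weighting follows the closed-neighborhood highest-core definition", {
  k5 <- clique_net(LETTERS[1:5])
  w <- mcode_vertex_weights(k5, degree_cutoff = 4)
  expect_true(all(w == 4))           # N[v] = K5: core 4, density 1
  # degree below the cutoff zeroes the weight
  edge <- net_from_pairs("A", "B")
  expect_true(all(mcode_vertex_weights(edge, degree_cutoff = 4) == 0))
  expect_true(all(mcode_vertex_weights(edge, degree_cutoff = 1) > 0))
})

test_that("vertex weighting equals an independent per-node evaluation on a random graph", {
  net <- random_gnp_net(60, 0.12, seed = 88)
  w <- mcode_vertex_weights(net, degree_cutoff = 4)
  adj <- adj_list(net)
  ed <- network_edges(net)
  ekey <- paste(ed$a, ed$b)
  for (v in names(adj)) {
    if (length(adj[[v]]) < 4) {
      expect_equal(w[[v]], 0)
      next
    }
    nbhd <- c(v, adj[[v]])
    sub_ed <- ed[ed$a %in% nbhd & ed$b %in% nbhd, ]
    sub <- ppi_network(sub_ed, nodes = nbhd)
    # highest core by repeated naive deletion at increasing k
    kmax <- 0
    while (length(oracle_kcore_nodes(sub, kmax + 1)) > 0) kmax <- kmax + 1
    core_nodes <- oracle_kcore_nodes(sub, kmax)
    core_edges <- sum(sub_ed$a %in% core_nodes & sub_ed$b %in% core_nodes)
    m <- length(core_nodes)
    expect_equal(w[[v]], kmax * 2 * core_edges / (m * (m - 1)),
                 tolerance = 1e-12)
  }
})

test_that("two planted cliques in a sparse background are recovered exactly", {
  cfg <- synthetic_config(seed = 101, n_nodes = 120, target_edges = 180,
                          max_degree = 3,
                          planted_modules = list(list(size = 6, density = 1),
                                                 list(size = 6, density = 1)),
                          disease_list_size = 50, target_list_size = 20,
                          overlap_count = 5, query_size = 30,
                          term_size_range = c(5, 20))
  sim <- generate_network(cfg)
  res <- mcode(sim$network)
  expect_length(res, 2L)
  got <- lapply(res, `[[`, "members")
  expect_setequal(got, sim$truth$modules)
  for (cl in res) {
    expect_equal(cl$score, 6)
    expect_equal(cl$n_edges, 15L)
    expect_true(cl$seed %in% cl$members)
  }
})

test_that("empty and all-low-degree networks yield no complexes", {
  empty <- ppi_network(data.frame(a = character(), b = character(),
                                  confidence = numeric()))
  expect_length(mcode(empty), 0L)
  sparse <- net_from_pairs("A","B", "B","C", "C","D")
  expect_length(mcode(sparse), 0L)  # all degrees < 4 -> all weights 0
})

test_that("cluster scoring reproduces density-times-size with validation", {
  expect_equal(score_cluster(3, 3), 3)
  for (n in c(2, 5, 9, 17))
    expect_equal(score_cluster(n, n * (n - 1) / 2), n)
  expect_equal(score_cluster(1, 0), 0)
  expect_error(score_cluster(4, 7), "exceeds")
  expect_equal(score_cluster(79, 881), 2 * 881 / 78)
})

test_that("clusters are vertex-disjoint, satisfy the k-core filter, and record true edge counts", {
  sim <- generate_network(synthetic_config(seed = 23))
  res <- mcode(filter_by_confidence(sim$network, 0.7))
  all_members <- unlist(lapply(res, `[[`, "members"))
  expect_false(any(duplicated(all_members)))
  ed <- network_edges(sim$network)
  ekey <- paste(ed$a, ed$b)
  for (cl in res) {
    pairs <- utils::combn(cl$members, 2)
    n_ind <- sum(paste(pairs[1, ], pairs[2, ]) %in% ekey)
    expect_equal(cl$n_edges, n_ind)
    expect_equal(cl$score, score_cluster(cl$n_nodes, cl$n_edges))
    sub <- ppi_network(ed[ed$a %in% cl$members & ed$b %in% cl$members, ])
    expect_gt(length(oracle_kcore_nodes(sub, 2)), 0)
  }
  # ranking: descending score, ties by size then seed
  scores <- vapply(res, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("haircut shaves singly-connected members; off keeps them", {
  # K5 plus a pendant; permissive score cutoff pulls the pendant in
  net <- clique_net(LETTERS[1:5],
                    extra = data.frame(a = "A", b = "P", confidence = 1))
  params_on <- mcode_params(degree_cutoff = 1, node_score_cutoff = 0.99,
                            haircut = TRUE)
  params_off <- mcode_params(degree_cutoff = 1, node_score_cutoff = 0.99,
                             haircut = FALSE)
  with_hc <- mcode(net, params_on)
  without <- mcode(net, params_off)
  expect_setequal(with_hc[[1]]$members, LETTERS[1:5])
  expect_setequal(without[[1]]$members, c(LETTERS[1:5], "P"))
})

test_that("max_depth bounds growth distance from the seed", {
  # chain of triangles: every node scores, growth walks the chain
  ed <- do.call(rbind, lapply(0:9, function(i) {
    a <- sprintf("v%02d", i); b <- sprintf("v%02d", i + 1)
    m <- sprintf("m%02d", i)
    data.frame(a = c(a, a, b), b = c(b, m, m), confidence = 1)
  }))
  net <- ppi_network(ed)
  p_deep <- mcode_params(degree_cutoff = 1, node_score_cutoff = 0.99,
                         max_depth = 100)
  p_shallow <- mcode_params(degree_cutoff = 1, node_score_cutoff = 0.99,
                            max_depth = 1)
  deep <- mcode(net, p_deep)
  shallow <- mcode(net, p_shallow)
  expect_equal(length(deep[[1]]$members), length(network_nodes(net)))
  expect_lt(length(shallow[[1]]$members), length(deep[[1]]$members))
})

test_that("mcode output is deterministic and serializes faithfully", {
  sim <- generate_network(synthetic_config(seed = 42, n_nodes = 200,
                                           target_edges = 1200,
                                           planted_modules = list(
                                             list(size = 12, density = 0.9))))
  r1 <- mcode(sim$network)
  r2 <- mcode(sim$network)
  expect_identical(lapply(r1, unclass), lapply(r2, unclass))
  f <- withr::local_tempfile(fileext = ".json")
  write_mcode(r1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$clusters$seed[1], r1[[1]]$seed)
  expect_equal(back$clusters$score[1], r1[[1]]$score)
  expect_equal(back$params$degree_cutoff, 4)
})
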