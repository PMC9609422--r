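test_that("parsing cleans self-loops and collapses duplicates keeping max confidence", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "B\tA\t0.8", "C\tC\t0.99"), f)
  net <- read_edge_list(f)
  expect_setequal(network_nodes(net), c("A", "B"))
  ed <- network_edges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$confidence, 0.9)
  expect_equal(net$metadata$n_self_loops_dropped, 1L)
  expect_equal(net$metadata$n_duplicates_collapsed, 1L)
})

test_that("a plain two-node edge parses as written", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tB\t0.5", f)
  net <- read_edge_list(f)
  expect_equal(network_summary(net)$n_nodes, 2L)
  expect_equal(network_summary(net)$n_edges, 1L)
})

test_that("headers and comments are skipped; two-column rows get the default confidence", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# exported network", "source\ttarget\tscore",
               "A\tB\t0.8", "B\tC"), f)
  net <- read_edge_list(f, default_confidence = 0.4)
  ed <- network_edges(net)
  expect_equal(ed$confidence[ed$a == "B"], 0.4)
  expect_equal(nrow(ed), 2L)
})

test_that("malformed rows and out-of-range confidences error with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "loner"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines(c("A\tB\t1.9"), f)
  expect_error(read_edge_list(f), "\\[0, 1\\]")
  writeLines(c("# only a comment"), f)
  expect_error(read_edge_list(f), "empty")
})

test_that("SIF parsing ignores the relation and fans out multi-target rows", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B C", "D pp A", "E"), f)
  net <- read_edge_list(f, default_confidence = 0.8)
  expect_setequal(network_nodes(net), c("A", "B", "C", "D", "E"))
  ed <- network_edges(net)
  expect_equal(nrow(ed), 3L)
  expect_true(all(ed$confidence == 0.8))
})

test_that("write/read round-trips a synthetic network exactly", {
  sim <- generate_network(synthetic_config(seed = 11, n_nodes = 150,
                                           target_edges = 900,
                                           planted_modules = list(
                                             list(size = 20, density = 0.6))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(sim$network, f)
  back <- read_edge_list(f)
  expect_equal(network_edges(back), network_edges(sim$network),
               ignore_attr = TRUE)
  expect_setequal(network_nodes(back), network_nodes(sim$network))
  # idempotence: a second round trip serializes byte-identically
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("confidence filtering is strict and drops isolated nodes", {
  net <- ppi_network(data.frame(a = c("A", "A", "C"), b = c("B", "C", "D"),
                                confidence = c(0.71, 0.70, 0.95)))
  filt <- filter_by_confidence(net, 0.7)
  ed <- network_edges(filt)
  expect_equal(nrow(ed), 2L)
  expect_setequal(paste(ed$a, ed$b), c("A B", "C D"))
  expect_equal(network_summary(filt)$n_nodes, 4L)
  expect_equal(filt$metadata$confidence_threshold, 0.7)
  # keep_isolated retains nodes that lose every edge
  filt2 <- filter_by_confidence(net, 0.9, keep_isolated = TRUE)
  expect_equal(network_summary(filt2)$n_nodes, 4L)
  expect_equal(network_summary(filt2)$n_edges, 1L)
})

test_that("threshold 0 is the identity on positive-confidence networks", {
  sim <- generate_network(synthetic_config(seed = 3, n_nodes = 60,
                                           target_edges = 200,
                                           planted_modules = list(),
                                           disease_list_size = 30,
                                           target_list_size = 10,
                                           overlap_count = 3,
                                           term_size_range = c(5, 15),
                                           query_size = 20))
  filt <- filter_by_confidence(sim$network, 0)
  expect_equal(network_edges(filt), network_edges(sim$network),
               ignore_attr = TRUE)
})

test_that("surviving edges match a brute-force count and filtering is monotone", {
  set.seed(42)
  n <- 80
  nodes <- sprintf("v%02d", 1:n)
  pairs <- utils::combn(nodes, 2)
  on <- sample(ncol(pairs), 500)
  ed <- data.frame(a = pairs[1, on], b = pairs[2, on],
                   confidence = runif(500))
  net <- ppi_network(ed)
  for (thr in c(0.3, 0.7, 0.95)) {
    got <- network_summary(filter_by_confidence(net, thr))$n_edges
    expect_equal(got, sum(ed$confidence > thr))
  }
  e1 <- network_edges(filter_by_confidence(net, 0.4))
  e2 <- network_edges(filter_by_confidence(net, 0.8))
  expect_true(all(paste(e2$a, e2$b) %in% paste(e1$a, e1$b)))
})

test_that("network summaries match definition and an O(V^2) density oracle", {
  k3 <- net_from_pairs("A","B", "B","C", "A","C")
  expect_equal(network_summary(k3),
               list(n_nodes = 3L, n_edges = 3L, density = 1,
                    n_components = 1L, largest_component_size = 3L),
               ignore_attr = TRUE)
  two <- net_from_pairs("A","B", "C","D")
  s <- network_summary(two)
  expect_equal(s$density, 1/3)
  expect_equal(s$n_components, 2L)
  expect_equal(s$largest_component_size, 2L)
  # density oracle: fraction of distinct pairs that are edges
  sim <- generate_network(synthetic_config(seed = 5, n_nodes = 40,
                                           target_edges = 120,
                                           planted_modules = list(),
                                           disease_list_size = 20,
                                           target_list_size = 8,
                                           overlap_count = 2,
                                           term_size_range = c(5, 10),
                                           query_size = 15))
  ed <- network_edges(sim$network)
  nn <- length(network_nodes(sim$network))
  pairs <- utils::combn(network_nodes(sim$network), 2)
  is_edge <- paste(pairs[1, ], pairs[2, ]) %in% paste(ed$a, ed$b)
  expect_equal(network_summary(sim$network)$density, mean(is_edge))
})

test_that("every operation preserves the simple-graph invariant", {
  sim <- generate_network(synthetic_config(seed = 9, n_nodes = 100,
                                           target_edges = 400,
                                           planted_modules = list(
                                             list(size = 10, density = 1))))
  for (net in list(sim$network,
                   filter_by_confidence(sim$network, 0.8),
                   k_core_subgraph(sim$network, 3))) {
    ed <- network_edges(net)
    expect_true(all(ed$a != ed$b))
    expect_false(any(duplicated(paste(ed$a, ed$b))))
    expect_true(all(c(ed$a, ed$b) %in% network_nodes(net)))
  }
})
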