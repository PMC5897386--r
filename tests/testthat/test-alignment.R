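test_that("pairwise identity matches hand-scored alignments", {
  pid <- pairwise_identity(c(a = "ACGT", b = "ACGA", c = "ACGT"))
  expect_equal(pid["a", "b"], 0.75)
  expect_equal(pid["a", "c"], 1)
  expect_equal(unname(diag(pid)), rep(1, 3))
  expect_equal(unclass(pid), t(unclass(pid)), ignore_attr = TRUE)
  expect_error(pairwise_identity(c(a = "ACGT")), "at least 2")
  expect_error(pairwise_identity(c(a = "ACGT", b = "")), "empty")
})

test_that("node score mixes sequence and topology linearly", {
  expect_equal(node_score("u", "v", 1, 0.8, 0.4), 0.8)
  expect_equal(node_score("u", "v", 0, 0.8, 0.4), 0.4)
  expect_equal(node_score("u", "v", 0.5, 0.8, 0.4), 0.6)
  expect_error(node_score("u", "v", 1.2, 1, 1), "alpha")
})

test_that("self-alignment returns the identity mapping with perfect scores", {
  dat <- sim_small(n_otus = 80, seed = 3)
  net <- truth_network(dat$truth, 1)
  ids <- otu_nodes(net)
  idm <- identity_seqsim(ids)
  for (a in c(0, 0.5, 1)) {
    aln <- align_networks(net, net, alpha = a, seqsim = idm)
    expect_true(all(aln$mapping$node1 == aln$mapping$node2))
    expect_equal(aln$ec, 100)
    expect_equal(aln$ss, 100)
  }
})

test_that("two matching dyads conserve their edge", {
  n1 <- coocnet(data.frame(name = c("u1", "u2"), kind = "OTU"),
                data.frame(node1 = "u1", node2 = "u2", sign = "copresence"))
  n2 <- coocnet(data.frame(name = c("v1", "v2"), kind = "OTU"),
                data.frame(node1 = "v1", node2 = "v2", sign = "copresence"))
  sim <- matrix(c(1, 0, 0, 1), 2, 2,
                dimnames = list(c("u1", "u2"), c("v1", "v2")))
  aln <- align_networks(n1, n2, alpha = 1, seqsim = sim)
  expect_equal(aln$ec, 100)
  expect_equal(nrow(aln$conserved), 1)
})

test_that("alignment is deterministic and invariant under consistent relabeling", {
  dat <- sim_small(n_otus = 80, seed = 3)
  n1 <- truth_network(dat$truth, 1)
  n2 <- truth_network(dat$truth, 2)
  a1 <- align_networks(n1, n2, alpha = 0)
  a2 <- align_networks(n1, n2, alpha = 0)
  expect_identical(a1$mapping, a2$mapping)
  # relabel both networks consistently: EC and SS are unchanged
  relabel <- function(g, prefix) {
    g2 <- g
    igraph::V(g2)$name <- paste0(prefix, igraph::V(g)$name)
    g2
  }
  b <- align_networks(relabel(n1, "x_"), relabel(n2, "y_"), alpha = 0)
  expect_equal(b$ec, a1$ec)
  expect_equal(b$ss, a1$ss)
})

test_that("EC and SS follow their formulas and orientation rules", {
  # 4-edge source, 6-edge induced image, 2 conserved -> EC 50, SS 25
  n1 <- coocnet(data.frame(name = paste0("a", 1:4), kind = "OTU"),
                data.frame(node1 = c("a1", "a1", "a1", "a2"),
                           node2 = c("a2", "a3", "a4", "a3"),
                           sign = "copresence"))
  n2 <- coocnet(data.frame(name = paste0("b", 1:4), kind = "OTU"),
                data.frame(node1 = c("b1", "b1", "b1", "b2", "b2", "b3"),
                           node2 = c("b2", "b3", "b4", "b3", "b4", "b4"),
                           sign = "copresence"))
  mapping <- data.frame(node1 = c("a1", "a2", "a3", "a4"),
                        node2 = c("b1", "b2", "b4", "b3"))
  sc <- alignment_scores(mapping, n1, n2)
  # conserved: a1-a2 -> b1-b2 (edge), a1-a3 -> b1-b4 (edge),
  # a1-a4 -> b1-b3 (edge), a2-a3 -> b2-b4 (edge): count exactly
  expect_equal(sc$ec, 100 * nrow(sc$conserved) / 4)
  expect_equal(sc$ss, 100 * nrow(sc$conserved) / (4 + 6 - nrow(sc$conserved)))
  # zero-conservation mapping
  n3 <- coocnet(data.frame(name = paste0("c", 1:4), kind = "OTU"),
                data.frame(node1 = "c1", node2 = "c2", sign = "copresence"))
  m0 <- data.frame(node1 = c("a1", "a2"), node2 = c("c1", "c3"))
  sc0 <- alignment_scores(m0, n1, n3)  # source is n3 (fewer edges)
  expect_equal(sc0$ec, 0)
  expect_equal(sc0$ss, 0)
  # empty source edge set reported as missing
  e0 <- coocnet(data.frame(name = c("z1", "z2"), kind = "OTU"))
  sce <- alignment_scores(data.frame(node1 = "a1", node2 = "z1"), n1, e0)
  expect_true(is.na(sce$ec))
})

test_that("EC never decreases when a conserved edge is added to both networks", {
  dat <- sim_small(n_otus = 80, seed = 3)
  n1 <- truth_network(dat$truth, 1)
  n2 <- truth_network(dat$truth, 2)
  ids1 <- otu_nodes(n1)
  map <- data.frame(node1 = ids1, node2 = ids1)
  map <- map[map$node2 %in% otu_nodes(n2), ]
  base <- alignment_scores(map, n1, n2)
  # add an edge between two mapped, currently unlinked nodes in both networks
  pick <- utils::head(map$node1[igraph::degree(n1)[map$node1] == 0], 2)
  if (length(pick) < 2) pick <- map$node1[1:2]
  if (!igraph::are_adjacent(n1, pick[1], pick[2])) {
    n1b <- igraph::add_edges(n1, pick)
    n2b <- if (!igraph::are_adjacent(n2, pick[1], pick[2]))
      igraph::add_edges(n2, pick) else n2
    after <- alignment_scores(map, n1b, n2b)
    expect_gte(after$ec, base$ec)
  }
})

test_that("alpha scan reports the full grid and a consensus weight", {
  dat <- sim_small(n_otus = 80, seed = 3)
  net <- truth_network(dat$truth, 1)
  idm <- identity_seqsim(otu_nodes(net))
  scan <- alpha_scan(net, net, grid = seq(0, 1, by = 0.1), seqsim = idm)
  expect_equal(nrow(scan$table), 11)
  expect_true(all(scan$table$ec == 100))
  # self-alignment ties at every alpha resolve to the smallest
  expect_equal(scan$consensus_alpha, 0)
  expect_equal(scan$table$n_self, rep(length(otu_nodes(net)), 11))
})

test_that("structured network pairs beat their randomisations", {
  dat <- sim_small(n_otus = 80, seed = 3)
  n1 <- truth_network(dat$truth, 1)
  n2 <- truth_network(dat$truth, 2)
  cz <- compare_to_random(n1, n2, n_random = 5, alpha = 0, seed = 31)
  expect_gt(cz$z_ec, 2)
  expect_gt(cz$ec, max(cz$random_ec))
  expect_error(compare_to_random(n1, n2, n_random = 0, alpha = 0), "n_random")
})

test_that("hiveplot export carries axes, sub-axes, ranks and sizes", {
  td <- withr::local_tempdir()
  dat <- sim_small(n_otus = 80, seed = 3)
  n1 <- truth_network(dat$truth, 1)
  n2 <- truth_network(dat$truth, 2)
  aln <- align_networks(n1, n2, alpha = 0)
  core <- dat$truth$core_set
  out <- hiveplot_export(aln, n1, n2, dat$otu, core,
                         file.path(td, "hive.json"))
  expect_true(file.exists(file.path(td, "hive.json")))
  expect_setequal(unique(out$nodes$axis), c(1, 2))
  expect_true(all(out$nodes$sub_axis %in% c("core", "noncore", "variable")))
  expect_true(all(out$nodes$degree_centrality >= 0))
  back <- jsonlite::read_json(file.path(td, "hive.json"))
  expect_equal(length(back$nodes), nrow(out$nodes))
})
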