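test_that("core decomposition is exact set arithmetic and symmetric", {
  mk <- function(ids) coocnet(data.frame(name = ids, kind = "OTU"))
  d <- core_decompose(mk(c("a", "b", "c")), mk(c("b", "c", "d")))
  expect_equal(d$core, c("b", "c"))
  expect_equal(d$noncore1, "a")
  expect_equal(d$noncore2, "d")
  # identical networks leave no noncore
  d2 <- core_decompose(mk(letters[1:4]), mk(letters[1:4]))
  expect_length(d2$noncore1, 0)
  expect_length(d2$noncore2, 0)
  # swapping inputs swaps the noncore sets, preserves the core
  ds <- core_decompose(mk(c("b", "c", "d")), mk(c("a", "b", "c")))
  expect_equal(ds$core, d$core)
  expect_equal(ds$noncore1, d$noncore2)
  expect_equal(ds$noncore2, d$noncore1)
  # published section sizes are mutually consistent: 476/591 OTUs sharing a
  # 232-OTU core leave 244 and 359 exclusives
  s1 <- sprintf("X%03d", 1:476)
  s2 <- c(s1[1:232], sprintf("Y%03d", 1:359))
  dp <- core_decompose(mk(s1), mk(s2))
  expect_length(dp$core, 232)
  expect_length(dp$noncore1, 244)
  expect_length(dp$noncore2, 359)
  # variables are excluded from the decomposition
  withvar <- coocnet(data.frame(name = c("a", "b", "pH"),
                                kind = c("OTU", "OTU", "VARIABLE")))
  expect_false("pH" %in% unlist(core_decompose(withvar, mk(c("a", "b")))))
})

test_that("aligned-to-self counts core fixed points", {
  aln <- list(mapping = data.frame(node1 = c("a", "b", "c"),
                                   node2 = c("a", "x", "c")))
  class(aln) <- "alignment_result"
  res <- aligned_to_self(aln, core = c("a", "b", "c"))
  expect_equal(res$count, 2)
  expect_equal(res$fraction, 2 / 3)
  expect_lte(res$count, 3)
  none <- aligned_to_self(list(mapping = data.frame(
    node1 = c("a", "b"), node2 = c("b", "a"))), core = c("a", "b"))
  expect_equal(none$count, 0)
  empty <- aligned_to_self(aln, core = character())
  expect_true(is.na(empty$fraction))
})

test_that("node flags mark hubs, abundant and environment-correlated OTUs", {
  # star graph: the centre is the unique hub at the default decile
  star <- igraph::make_star(11, mode = "undirected")
  igraph::V(star)$name <- c("hub", sprintf("leaf%02d", 1:10))
  igraph::V(star)$kind <- "OTU"
  counts <- matrix(rpois(11 * 6, 50), 11, 6,
                   dimnames = list(igraph::V(star)$name, paste0("S", 1:6)))
  t <- otu_table(counts)
  fl <- flag_nodes(star, t)
  expect_equal(fl$node[fl$is_hub], "hub")
  # uniform abundances 1/11 > 0.1% -> all abundant
  expect_true(all(fl$is_abundant))
  # no significant correlations -> empty flags
  expect_true(all(fl$env_correlated == ""))
  # a strongly pH-tracking OTU gets flagged
  ab <- abiotic_table(matrix(seq(8, 6, length.out = 6), 1, 6,
                             dimnames = list("pH", paste0("S", 1:6))))
  counts["hub", ] <- round(seq(1000, 10, length.out = 6))
  t2 <- otu_table(counts)
  fl2 <- flag_nodes(star, t2, ab, variables = "pH")
  expect_true(grepl("pH", fl2$env_correlated[fl2$node == "hub"]))
})

test_that("rule application matches lineages at the stated rank", {
  rules <- rule_set(data.frame(
    rank = c("genus", "genus", "phylum"),
    pattern = c("g__Nitrospira", "g__Nitrospira", "p__Cyanobacteria"),
    category = c("nitrification", "nitrite_oxidation", "photosynthesis")))
  tax <- c(A = "k__Bacteria; p__Nitrospirae; g__Nitrospira",
           B = "k__Bacteria; p__Cyanobacteria; g__Nostoc",
           C = "k__Bacteria; p__Firmicutes; g__Bacillus")
  lab <- apply_rules(rules, tax)
  expect_setequal(lab$A, c("nitrification", "nitrite_oxidation"))
  expect_equal(lab$B, "photosynthesis")
  expect_length(lab$C, 0)
  bad <- data.frame(rank = "species", pattern = "s__x", category = "c")
  expect_error(apply_rules(rule_set(bad), tax), "rank")
})

test_that("function profiles are per-site shares with scale invariance", {
  t <- toy_otu()
  labels <- list(OTU1 = "chemoheterotrophy", OTU2 = character(),
                 OTU3 = c("nitrification", "chemoheterotrophy"))
  pr <- function_profile(c("OTU1", "OTU3"), t, labels, sites = 1:2)
  ps <- attr(pr, "per_site")
  rel <- relative_abundance(t)
  site1 <- t$sample_meta$sample[t$sample_meta$site == 1]
  # share of the set's abundance held by nitrification-labelled members
  expect_equal(ps["nitrification", "1"],
               mean(rel["OTU3", site1] /
                      colSums(rel[c("OTU1", "OTU3"), site1])) * 100)
  # doubling all counts leaves shares unchanged
  t2 <- otu_table(t$counts * 2, sample_meta = t$sample_meta)
  pr2 <- function_profile(c("OTU1", "OTU3"), t2, labels, sites = 1:2)
  expect_equal(pr2$mean, pr$mean)
  # empty set gives an all-zero profile
  pr0 <- function_profile(character(), t, labels, sites = 1:2)
  expect_true(all(pr0$mean == 0))
  # mixture: the whole community's share lies between a set's and its
  # complement's shares
  prA <- function_profile("OTU3", t, labels, sites = 1:2)
  prB <- function_profile(c("OTU1", "OTU2"), t, labels, sites = 1:2)
  prAll <- function_profile(rownames(t$counts), t, labels, sites = 1:2)
  pa <- attr(prA, "per_site"); pb <- attr(prB, "per_site")
  pall <- attr(prAll, "per_site")
  expect_true(all(pall >= pmin(pa, pb) - 1e-9 & pall <= pmax(pa, pb) + 1e-9))
})

test_that("profile comparisons use t-tests for two groups and ANOVA beyond", {
  t <- sim_small()$otu
  lab <- sim_small()$labels
  core <- sim_small()$truth$core_set
  p1 <- function_profile(core, t, lab, sites = 1:8, group = "core")
  p2 <- function_profile(setdiff(rownames(t$counts), core), t, lab,
                         sites = 1:8, group = "rest")
  two <- compare_profiles(list(core = p1, rest = p2))
  expect_true(all(two$test[!is.na(two$test)] == "t"))
  three <- compare_profiles(list(a = p1, b = p2, c = p1))
  expect_true(all(three$test[!is.na(three$test)] == "anova"))
  expect_true(all(three$category %in% union(p1$category, p2$category)))
  # identical groups are never significant
  same <- compare_profiles(list(a = p1, b = p1))
  expect_true(all(same$p[!is.na(same$p)] > 0.5))
  # groups far apart at n = 4 sites are detected
  m1 <- p1; m2 <- p1
  attr(m2, "per_site") <- attr(p1, "per_site")[, 1:4] + 10
  attr(m1, "per_site") <- attr(p1, "per_site")[, 1:4]
  apart <- compare_profiles(list(a = m1, b = m2))
  expect_true(any(apart$p < 0.05, na.rm = TRUE))
})
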