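test_that("pair scores match closed forms", {
  x <- c(1, 2, 3, 4)
  expect_equal(pair_score(x, 2 * x, "pearson"), 1)
  expect_equal(pair_score(x, 2 * x, "spearman"), 1)
  expect_equal(pair_score(x, x, "bray-curtis"), 0)
  expect_equal(pair_score(c(1, 1, 0, 0), c(0, 0, 1, 1), "bray-curtis"), 1)
  expect_equal(pair_score(x, x, "kullback-leibler"), 0)
  expect_gt(pair_score(c(10, 0, 0, 0), c(0, 0, 0, 10), "kullback-leibler"), 0)
  expect_true(is.na(pair_score(rep(1, 4), x, "pearson")))
  expect_error(pair_score(1:3, 1:3, "pearson"), "at least 4")
})

test_that("candidate selection keeps only pairs consistent across all four measures", {
  # three OTUs: A and B strongly co-vary, C is independent noise
  set.seed(4)
  n <- 12
  base <- exp(rnorm(n, 5, 1))
  counts <- rbind(A = rpois(n, base), B = rpois(n, base),
                  C = rpois(n, exp(rnorm(n, 5, 1))),
                  D = rpois(n, 150), E = rpois(n, 150))
  colnames(counts) <- paste0("S", 1:n)
  t <- otu_table(counts)
  cand <- select_candidates(t, n_pos = 1, n_neg = 1, minocc = 1)
  expect_true(any(cand$node1 == "A" & cand$node2 == "B" &
                    cand$sign == "copresence"))

  # a pair top-ranked by only three measures is excluded: force disagreement
  # by checking that every candidate is inside each measure's nomination set
  dat <- sim_small()
  s1 <- filter_min_samples(section_slice(dat$otu, 1), 5)
  cand <- select_candidates(s1, n_pos = 200, n_neg = 200)
  counts1 <- s1$counts[rowSums(s1$counts > 0) >= 10, ]
  sm <- score_matrices(counts1)
  nodes <- rownames(counts1)
  iu <- which(upper.tri(sm$pearson), arr.ind = TRUE)
  key <- paste(nodes[iu[, 1]], nodes[iu[, 2]])
  P <- sum(complete.cases(sapply(sm, `[`, iu)))
  for (m in names(sm)) {
    s <- sm[[m]][iu]
    r <- rank(if (m %in% c("pearson", "spearman")) -s else s,
              ties.method = "first")
    pos_keys <- key[r <= 200]
    got <- paste(cand$node1[cand$sign == "copresence"],
                 cand$node2[cand$sign == "copresence"])
    expect_true(all(got %in% pos_keys))
  }
  # sign conservation: co-presence edges have positive correlations
  expect_true(all(cand$pearson[cand$sign == "copresence"] > 0))
  expect_true(all(cand$spearman[cand$sign == "copresence"] > 0))
  expect_true(all(cand$pearson[cand$sign == "exclusion"] < 0))

  # row/sample order invariance
  s1p <- subset_otu_table(s1, otus = rev(rownames(s1$counts)),
                          samples = rev(colnames(s1$counts)))
  cand_p <- select_candidates(s1p, n_pos = 200, n_neg = 200)
  keyfun <- function(d) sort(paste(d$node1, d$node2, d$sign))
  expect_equal(keyfun(cand_p), keyfun(cand))
})

test_that("threshold-free limit returns all pairs with agreed sign", {
  set.seed(11)
  counts <- matrix(rpois(6 * 12, 40), 6, 12,
                   dimnames = list(letters[1:6], paste0("S", 1:12)))
  t <- otu_table(counts)
  cand <- suppressWarnings(
    select_candidates(t, n_pos = 10000, n_neg = 10000, minocc = 1))
  expect_warning(select_candidates(t, n_pos = 10000, n_neg = 10000,
                                   minocc = 1), "fewer rankable")
  # every candidate pair appears once with a single sign
  expect_false(any(duplicated(paste(cand$node1, cand$node2))))
})

test_that("reboot edge test is deterministic, calibrated and powerful", {
  set.seed(5)
  x <- round(exp(rnorm(12, 4, 1)))
  y <- round(exp(rnorm(12, 4, 1)))
  tot <- x + y + rpois(12, 4000)
  r1 <- reboot_edge_test(x, y, tot, "pearson", n = 300, seed = 7)
  r2 <- reboot_edge_test(x, y, tot, "pearson", n = 300, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$ci[1] <= r1$ci[2])

  # duplicated profiles are detected at p < 0.001
  d <- round(exp(rnorm(12, 5, 1)))
  rd <- reboot_edge_test(d, d, d + d + 3000, "pearson", n = 1000, seed = 3)
  expect_lt(rd$p, 0.001)
  expect_false(rd$killed)

  # calibration at reduced scale (full 500-pair check in the acceptance suite)
  set.seed(6)
  rej <- vapply(1:150, function(i) {
    a <- round(exp(rnorm(12, 4, 1)))
    b <- round(exp(rnorm(12, 4, 1)))
    reboot_edge_test(a, b, a + b + rpois(12, 4000), "pearson",
                     n = 200, seed = 9000 + i)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.015)
  expect_lt(mean(rej), 0.095)
})

test_that("p-value merging follows Brown/Fisher and BH", {
  # single measure passes through
  one <- merge_and_correct(matrix(0.01, 1, 1))
  expect_equal(one$p_merged, 0.01, tolerance = 1e-9)
  # all-ones merge to 1
  ones <- merge_and_correct(matrix(1, 1, 4))
  expect_equal(ones$p_merged, 1, tolerance = 1e-6)
  expect_equal(ones$q, 1, tolerance = 1e-6)
  # four independent p = 0.05 beat 0.05 under Fisher (chi-square 8 df at 23.97)
  four <- merge_and_correct(matrix(0.05, 1, 4))
  expect_equal(four$p_merged, pchisq(-2 * 4 * log(0.05), df = 8,
                                     lower.tail = FALSE), tolerance = 1e-9)
  expect_lt(four$p_merged, 0.05)
  # BH ordering preserved across edges
  pm <- matrix(c(0.001, 0.5, 0.01, 0.9), 2, 2)
  mg <- merge_and_correct(pm)
  expect_lt(mg$q[1], mg$q[2])
})

test_that("build_network assembles signed edges with q-values and stats hold", {
  dat <- sim_small()
  s1 <- filter_min_samples(section_slice(dat$otu, 1), 5)
  ab <- abiotic_table(dat$abiotic$values[, colnames(s1$counts)])
  net <- build_network(s1, ab, n_perm = 100, seed = 13)
  expect_s3_class(net, "coocnet")
  expect_gt(igraph::ecount(net), 0)
  expect_true(all(igraph::edge_attr(net, "sign") %in%
                    c("copresence", "exclusion")))
  q <- igraph::edge_attr(net, "q")
  expect_true(all(q >= 0 & q < 0.05))
  kind <- igraph::vertex_attr(net, "kind")
  vars <- igraph::V(net)$name[kind == "VARIABLE"]
  expect_true(all(vars %in% c("pH", "RelativeHumidity", "Temperature",
                              "N_total", "C_total", "P", "S", "Cu",
                              "Fe", "Zn")))
  # recovery against the planted truth is far above chance
  rec <- edge_recovery(net, dat$truth, 1)
  expect_gt(rec$f1, 0.5)
  expect_gt(rec$sign_accuracy, 0.95)
})

test_that("association-free data yields a near-empty network", {
  set.seed(17)
  counts <- matrix(rpois(60 * 12, exp(rnorm(60 * 12, 4, 1))), 60, 12,
                   dimnames = list(sprintf("O%02d", 1:60), paste0("S", 1:12)))
  t <- otu_table(counts)
  cand <- select_candidates(t, n_pos = 500, n_neg = 500, minocc = 10)
  net <- suppressWarnings(build_network(t, NULL, n_pos = 500, n_neg = 500,
                                        minocc = 10, n_perm = 100, seed = 19))
  expect_lt(igraph::ecount(net), 0.05 * max(1, nrow(cand)) + 3)
})

test_that("network statistics match hand-computed values", {
  st <- network_stats(k3_net())
  expect_equal(st$clustering, 1)
  expect_equal(st$density, 1)
  expect_equal(st$heterogeneity, 0)
  expect_equal(st$path_length, 1)
  st2 <- network_stats(p3_net())
  expect_equal(st2$clustering, 0)
  expect_equal(st2$density, 2 / 3)
  expect_equal(st2$path_length, 4 / 3)
  # k-regular graph has zero heterogeneity
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- letters[1:8]
  expect_equal(network_stats(ring)$heterogeneity, 0)
})

test_that("degree-distribution verdict separates Poisson from power-law degrees", {
  set.seed(23)
  pois_hits <- mean(replicate(15, degree_distribution_verdict(rpois(500, 5)) ==
                                "erdos-renyi-like"))
  expect_gte(pois_hits, 0.9)
  kmax <- 50000
  pz <- (1:kmax)^-2.5; pz <- pz / sum(pz)
  pl_hits <- mean(replicate(15, degree_distribution_verdict(
    sample.int(kmax, 500, TRUE, pz)) == "power-law-like"))
  expect_gte(pl_hits, 0.9)
  expect_equal(degree_distribution_verdict(rpois(10, 4)), "inconclusive")
})

test_that("edge-shuffling randomisation preserves nodes and edge count", {
  dat <- sim_small()
  net <- truth_network(dat$truth, 1)
  for (sd in 1:5) {
    rn <- randomize_network(net, seed = sd)
    expect_setequal(igraph::V(rn)$name, igraph::V(net)$name)
    expect_equal(igraph::ecount(rn), igraph::ecount(net))
    expect_equal(sum(igraph::which_loop(rn)), 0)
    expect_equal(sum(igraph::which_multiple(rn)), 0)
  }
  # repeated application decorrelates the degree sequence
  d0 <- igraph::degree(net)
  r1 <- randomize_network(net, seed = 1)
  r2 <- randomize_network(r1, seed = 2)
  c1 <- cor(d0, igraph::degree(r1)[names(d0)])
  expect_lt(c1, 1)
  # empty network is unchanged
  empty <- coocnet(data.frame(name = letters[1:4], kind = "OTU"))
  expect_equal(igraph::ecount(randomize_network(empty, 1)), 0)
})
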